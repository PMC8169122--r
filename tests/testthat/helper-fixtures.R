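# Shared fixtures, built in code at test time.

default_params <- cell_cycle_params()

# A small clonal population laid out on a non-overlapping grid.
grid_population <- function(n_founders = 12, n_cells = 48, seed = 3) {
  m <- lenti_mix_model(n_founders = n_founders, seed = seed)
  pop <- make_lenti_population(m, n_cells)
  side_x <- ceiling(sqrt(n_cells * 4 / 3))
  side_y <- ceiling(n_cells / side_x)
  g <- expand.grid(x = seq(0.06, 0.94, length.out = side_x),
                   y = seq(0.06, 0.94, length.out = side_y))
  g <- g[seq_len(n_cells), ]
  pop$x <- g$x
  pop$y <- g$y
  pop
}

# RGB record table straight from a population's true colours (no imaging).
population_records <- function(pop) {
  data.frame(cell_id = pop$cell_id, image_id = "truth",
             x = 0, y = 0,
             mean_r = pop$r, mean_g = pop$g, mean_b = pop$b)
}

# One record at every combination of per-channel bin centres.
bin_centre_sweep <- function(bins = 8L) {
  centres <- (seq_len(bins) - 0.5) / bins * 65536
  g <- expand.grid(mean_r = centres, mean_g = centres, mean_b = centres)
  data.frame(cell_id = seq_len(nrow(g)), g)
}
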