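# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

tiny_scenario <- function(N = 12L, sizes = c(4L, 4L, 4L),
                          end = "2018-01-14") {
  sc <- default_scenario()
  sc$N <- N
  sc$K <- length(sizes)
  sc$membership_sizes <- sizes
  sc$end <- end
  sc$layers <- sc$layers[seq_len(sc$K)]
  sc
}

# Write a small detection-log file and return its path.
write_log_file <- function(lines, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("logdir")
    dir.create(dir)
  }
  path <- file.path(dir, "log.csv")
  writeLines(c("timestamp,observer_id,observed_id", lines), path)
  path
}

# A random nonnegative integer matrix wrapped as a contact_matrix over a
# one-day grid (truncating J to n_pairs of the id set).
random_contact_matrix <- function(n_ids, seed, lambda = 1) {
  set.seed(seed)
  ids <- sprintf("p%02d", seq_len(n_ids))
  dyads <- build_dyad_index(ids)
  grid <- build_epoch_grid("2018-01-01", "2018-01-01", 30)
  Y <- matrix(rpois(grid$I * dyads$J, lambda), grid$I, dyads$J)
  proxnet:::new_contact_matrix(Matrix::Matrix(Y, sparse = TRUE), grid, dyads)
}

# Exactly orthogonal unit-variance item pair with sample correlation rho;
# alpha and omega have closed forms for it.
parallel_item_pair <- function(rho, n = 8L) {
  stopifnot(n %% 4 == 0)
  z1 <- rep(c(1, 1, -1, -1), n / 4)
  z2 <- rep(c(1, -1, 1, -1), n / 4)
  cbind(item1 = z1, item2 = rho * z1 + sqrt(1 - rho^2) * z2)
}
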