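# shared fixtures built in code

# brute-force double-loop convolution (independent oracle for convolve_mtrf)
brute_convolve <- function(x_values, kernel_values, lag0) {
  p <- nrow(x_values)
  n <- ncol(x_values)
  L <- dim(kernel_values)[2L]
  C <- dim(kernel_values)[3L]
  out <- matrix(0, C, n)
  for (ch in seq_len(C)) {
    for (t in seq_len(n)) {
      acc <- 0
      for (i in seq_len(p)) {
        for (l in seq_len(L)) {
          src <- t - (lag0 + l - 1L)
          if (src >= 1L && src <= n) acc <- acc + kernel_values[i, l, ch] * x_values[i, src]
        }
      }
      out[ch, t] <- acc
    }
  }
  out
}

random_instance <- function(seed, n_max = 300L, p_max = 4L, c_max = 3L) {
  set.seed(seed)
  n <- sample(50:n_max, 1L)
  p <- sample(seq_len(p_max), 1L)
  C <- sample(seq_len(c_max), 1L)
  L <- sample(3:15, 1L)
  lag0 <- sample(-5:10, 1L)
  list(
    x = matrix(stats::rnorm(p * n), p, n),
    h = array(stats::rnorm(p * L * C), c(p, L, C)),
    n = n, lag0 = lag0,
    tstep = 0.01
  )
}

# small simulated recovery scenario shared by several tests
small_sim <- function(seed, duration = 30, n_bands = 2L, n_channels = 1L,
                      tmax = 0.4, snr_db = 0, rho = 0.5) {
  spec <- sim_spec(
    duration = duration, rate = 100,
    truth = ground_truth_kernel(n_bands = n_bands, n_channels = n_channels,
                                tmax = tmax),
    band_correlation = rho, snr_db = snr_db, seed = seed
  )
  simulate_dataset(spec)
}

kernel_correlation <- function(fit_kernel, truth) {
  C <- dim(truth$values)[3L]
  vapply(seq_len(C), function(ch) {
    stats::cor(as.vector(fit_kernel$values[, , ch]),
               as.vector(truth$values[, , ch]))
  }, 0)
}

# 4 x 4 sensor grid and its adjacency
grid_sensors <- function() {
  coords <- as.matrix(expand.grid(x = 1:4, y = 1:4))
  rownames(coords) <- paste0("s", 1:16)
  coords
}

grid_adjacency <- function() {
  build_adjacency(grid_sensors(), 1.5)
}

# long-format null group table on the grid (optionally with an effect on the
# first `n_effect` sensors)
grid_group_table <- function(seed, n_subjects = 12L, effect = 0,
                             n_effect = 5L) {
  set.seed(seed)
  vals <- matrix(stats::rnorm(n_subjects * 16L), n_subjects, 16L)
  if (effect > 0) vals[, seq_len(n_effect)] <- vals[, seq_len(n_effect)] + effect
  tibble::tibble(
    subject = rep(seq_len(n_subjects), each = 16L),
    condition = "diff",
    sensor = rep(paste0("s", 1:16), n_subjects),
    value = as.vector(t(vals))
  )
}

segment_samples_for_test <- function(p, segs) {
  unlist(lapply(segs, function(s) {
    seq.int(p$segments$start[s], p$segments$end[s])
  }), use.names = FALSE)
}

fit_backward_lag_count <- function(fit) fit$kernel$lag_axis$n_samples
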