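#' Paired (related-measures) t-test
#'
#' Thin wrapper around [stats::t.test()] for paired per-subject outcomes
#' (e.g. predictive power of two models), returning the statistic, degrees of
#' freedom (`n - 1`) and two-tailed p-value. Identical conditions (all
#' differences zero) return `t = 0, p = 1` rather than an error.
#'
#' @param a,b Numeric vectors of per-subject outcomes, same length and order.
#' @return A list with `t`, `df`, `p`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 paired subjects", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = length(d) - 1L, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Average an outcome map over a sensor subset
#'
#' @param map Named numeric vector (one value per sensor) or a sensors-by-time
#'   matrix with sensor rownames.
#' @param sensors Character vector of sensor labels.
#' @return Unweighted mean over the subset (scalar, or per-time vector for a
#'   matrix input).
#' @export
average_sensors <- function(map, sensors) {
  if (!length(sensors)) stop("`sensors` must be non-empty", call. = FALSE)
  labels <- if (is.matrix(map)) rownames(map) else names(map)
  missing <- setdiff(sensors, labels)
  if (length(missing)) {
    stop("unknown sensor label(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.matrix(map)) colMeans(map[sensors, , drop = FALSE])
  else mean(map[sensors])
}

#' Sensor adjacency from coordinates
#'
#' Builds an explicit neighbor list by connecting sensors closer than
#' `threshold`. Disconnected sensors are allowed (they form their own
#' clusters) but reported via a message.
#'
#' @param coords Numeric matrix (sensors x spatial dims) with rownames, or a
#'   data frame with columns `sensor`, `x`, `y` (and optionally `z`).
#' @param threshold Connection distance in the units of `coords`.
#' @return A tibble with columns `from`, `to` (each undirected pair once).
#' @export
build_adjacency <- function(coords, threshold) {
  if (is.data.frame(coords)) {
    labels <- as.character(coords$sensor)
    coords <- as.matrix(coords[, intersect(c("x", "y", "z"), names(coords))])
    rownames(coords) <- labels
  }
  labels <- rownames(coords)
  if (is.null(labels)) stop("`coords` needs sensor labels (rownames)", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  pairs <- which(d < threshold & upper.tri(d), arr.ind = TRUE)
  out <- tibble::tibble(from = labels[pairs[, 1L]], to = labels[pairs[, 2L]])
  isolated <- setdiff(labels, unique(c(out$from, out$to)))
  if (length(isolated)) {
    message("sensors with no neighbors: ", paste(isolated, collapse = ", "))
  }
  out
}

# neighbor index list per element of a (sensor x time) grid, from a sensor
# pair table; time adds contiguity links
element_adjacency <- function(sensor_labels, adjacency, n_time = 1L) {
  n_s <- length(sensor_labels)
  nb_s <- lapply(seq_len(n_s), function(i) integer())
  if (nrow(adjacency)) {
    fi <- match(adjacency$from, sensor_labels)
    ti <- match(adjacency$to, sensor_labels)
    if (anyNA(fi) || anyNA(ti)) {
      stop("adjacency names sensors absent from the data", call. = FALSE)
    }
    for (r in seq_along(fi)) {
      nb_s[[fi[r]]] <- c(nb_s[[fi[r]]], ti[r])
      nb_s[[ti[r]]] <- c(nb_s[[ti[r]]], fi[r])
    }
  }
  # element index e = (t - 1) * n_s + s
  lapply(seq_len(n_s * n_time), function(e) {
    s <- (e - 1L) %% n_s + 1L
    t0 <- (e - 1L) %/% n_s + 1L
    nbrs <- (t0 - 1L) * n_s + nb_s[[s]]
    if (t0 > 1L) nbrs <- c(nbrs, e - n_s)
    if (t0 < n_time) nbrs <- c(nbrs, e + n_s)
    as.integer(nbrs)
  })
}

# long group table -> subjects x elements difference matrix
group_table_to_diffs <- function(table, conditions = NULL) {
  stopifnot(all(c("subject", "condition", "sensor", "value") %in% names(table)))
  has_time <- "time" %in% names(table) && length(unique(table$time)) > 1L
  if (is.null(conditions)) conditions <- sort(unique(table$condition))
  if (length(conditions) != 2L) {
    stop("need exactly two conditions (or a one-sample table of differences)",
         call. = FALSE)
  }
  sensors <- unique(table$sensor)
  times <- if (has_time) sort(unique(table$time)) else 0
  subjects <- unique(table$subject)
  shape <- function(cond) {
    sub <- table[table$condition == cond, , drop = FALSE]
    m <- matrix(NA_real_, length(subjects), length(sensors) * length(times))
    s_i <- match(sub$subject, subjects)
    sen_i <- match(sub$sensor, sensors)
    t_i <- if (has_time) match(sub$time, times) else rep(1L, nrow(sub))
    e_i <- (t_i - 1L) * length(sensors) + sen_i
    m[cbind(s_i, e_i)] <- sub$value
    if (anyNA(m)) stop("each subject must appear once per condition and element",
                       call. = FALSE)
    m
  }
  list(diffs = shape(conditions[2L]) - shape(conditions[1L]),
       sensors = sensors, times = times, has_time = has_time,
       conditions = conditions)
}

# vectorized sign-flip t maps: S (m x n subjects in {-1, 1}), D (n x e)
signflip_t <- function(S, D) {
  n <- nrow(D)
  M <- (S %*% D) / n
  ssq <- matrix(colSums(D^2), nrow(S), ncol(D), byrow = TRUE)
  v <- (ssq - n * M^2) / (n - 1)
  v[v < 0] <- 0
  T <- M / sqrt(v / n)
  T[!is.finite(T)] <- 0
  T
}

#' Mass-univariate cluster-based permutation test
#'
#' Tests a paired two-condition (or one-sample) effect across sensor (and
#' optionally time) maps while controlling the family-wise error. An
#' element-wise related-measures t map is thresholded (two-tailed t at
#' `cluster_p` by default); suprathreshold elements are grouped into
#' connected clusters (sensor adjacency, plus temporal contiguity when a time
#' axis is present), positive and negative clusters separately, and scored by
#' their mass (sum of t). The null distribution of the maximum absolute
#' cluster mass is built from random sign flips of the subject difference
#' maps — exhaustively when `2^n <= n_permutations`, otherwise by Monte Carlo
#' with `(b + 1) / (m + 1)` p-values.
#'
#' @param table Long-format group table: columns `subject`, `condition`,
#'   `sensor`, optional `time`, `value`. With a single condition the values
#'   are treated as paired differences (one-sample test against 0).
#' @param adjacency Sensor neighbor table with columns `from`, `to` (see
#'   [build_adjacency()]). May be empty for a single sensor.
#' @param alpha Significance level for reporting (family-wise).
#' @param n_permutations Maximum number of permutations.
#' @param cluster_threshold Cluster-forming t threshold; default the
#'   two-tailed critical t at `cluster_p` with `n - 1` df.
#' @param cluster_p Tail probability for the default threshold.
#' @param seed Seed for Monte-Carlo sign flips.
#' @return An object of class `cluster_result`: the t map, cluster labels,
#'   a tibble of clusters (id, mass, p), the threshold, and the permutation
#'   count and kind.
#' @export
cluster_permutation_test <- function(table, adjacency, alpha = 0.05,
                                     n_permutations = 10000L,
                                     cluster_threshold = NULL,
                                     cluster_p = 0.05, seed = 1L) {
  conds <- sort(unique(table$condition))
  if (length(conds) == 1L) {
    tbl <- table
    tbl$condition <- "zero"
    tbl$value <- 0
    table <- rbind(tbl, table)
    conds <- c("zero", conds[1L])
  }
  g <- group_table_to_diffs(table, conds)
  D <- g$diffs
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (n_permutations < 100L) {
    warning("fewer than 100 permutations gives unstable p-values")
  }
  if (is.null(cluster_threshold)) {
    cluster_threshold <- stats::qt(1 - cluster_p / 2, df = n - 1L)
  }
  adj_list <- element_adjacency(g$sensors, adjacency,
                                n_time = length(g$times))

  t_obs <- drop(signflip_t(matrix(1, 1L, n), D))
  comp <- cluster_components_cpp(t_obs, adj_list, cluster_threshold)
  labels <- comp$labels
  masses <- comp$masses

  exhaustive <- n <= 30 && 2^n <= n_permutations
  if (exhaustive) {
    m <- 2^n
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    m <- as.integer(n_permutations)
    set.seed(seed)
    S <- matrix(sample(c(-1, 1), m * n, replace = TRUE), m, n)
  }
  Tnull <- signflip_t(S, D)
  null_max <- max_cluster_mass_cpp(Tnull, adj_list, cluster_threshold)

  p_vals <- vapply(masses, function(ms) {
    b <- sum(null_max >= abs(ms))
    if (exhaustive) b / m else (b + 1) / (m + 1)
  }, 0)

  clusters <- tibble::tibble(
    id = seq_along(masses),
    mass = masses,
    n_elements = vapply(seq_along(masses), function(i) sum(labels == i), 0L),
    p = p_vals,
    significant = p_vals <= alpha
  )
  dim_t <- if (g$has_time) c(length(g$sensors), length(g$times)) else NULL
  t_map <- t_obs
  label_map <- labels
  if (!is.null(dim_t)) {
    t_map <- matrix(t_obs, dim_t[1L], dim_t[2L], dimnames = list(g$sensors, g$times))
    label_map <- matrix(labels, dim_t[1L], dim_t[2L],
                        dimnames = list(g$sensors, g$times))
  } else {
    names(t_map) <- g$sensors
    names(label_map) <- g$sensors
  }
  structure(
    list(t_map = t_map, cluster_labels = label_map, clusters = clusters,
         threshold = cluster_threshold, alpha = alpha,
         n_permutations = if (exhaustive) m else m,
         exhaustive = exhaustive, null_max = null_max,
         sensors = g$sensors, times = if (g$has_time) g$times else NULL,
         conditions = g$conditions, n_subjects = n),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d subjects, threshold |t| > %.3f, %s %d permutations\n",
              x$n_subjects, x$threshold,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo", x$n_permutations))
  if (nrow(x$clusters)) print(x$clusters) else cat("  no suprathreshold clusters\n")
  invisible(x)
}
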