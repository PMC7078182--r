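#' Default fertility grid for transition sweeps
#'
#' Twelve fertility levels log-spaced on \[1, 8\] offspring per couple.
#' At the full scale (n = 500, nu = 60) this spans realised friend ratios
#' from roughly 0.3 (kin-rich) to 1 (kin-free); the friend ratio is always
#' measured on the realised networks, never assumed from fertility.
#'
#' @param levels Number of grid points.
#' @param from,to Grid end points (offspring per couple).
#' @return Numeric vector of fertility levels.
#' @export
default_fertility_grid <- function(levels = 12L, from = 1, to = 8) {
  exp(seq(log(from), log(to), length.out = levels))
}

#' Configuration of a fertility sweep
#'
#' @param fertility_grid Sorted vector of positive fertility levels.
#' @param replicates Replicates per fertility level (>= 1).
#' @param algorithms Subset of `c("homophily", "weighted", "random")`.
#' @param n Number of egos per network.
#' @param nu Degree target.
#' @param cost_params A [cost_params()] object for the weighted heuristic.
#' @param base_seed Integer master seed; every kin network, trait vector
#'   and algorithm run draws its own seed from it by a stable hash, so the
#'   whole sweep is reproducible and the three algorithms see the *same*
#'   kin network and traits within each replicate (paired design).
#' @param family_size_law,binomial_max Passed to [pedigree_params()].
#' @param trait_low,trait_high Trait distribution bounds.
#' @param tiebreak Tie-break policy for the friend-choice steps.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(fertility_grid = default_fertility_grid(),
                         replicates = 10L,
                         algorithms = c("homophily", "weighted", "random"),
                         n = 500L, nu = 60L,
                         cost_params = homophilynet::cost_params(),
                         base_seed = 1L,
                         family_size_law = "binomial", binomial_max = 8L,
                         trait_low = 0, trait_high = 100,
                         tiebreak = "random") {
  stopifnot(length(fertility_grid) >= 1, all(fertility_grid > 0),
            !is.unsorted(fertility_grid), replicates >= 1,
            all(algorithms %in% c("homophily", "weighted", "random")),
            length(algorithms) >= 1, n >= 2, nu >= 2)
  structure(list(fertility_grid = fertility_grid,
                 replicates = as.integer(replicates),
                 algorithms = algorithms, n = as.integer(n),
                 nu = as.integer(nu), cost_params = cost_params,
                 base_seed = as.integer(base_seed),
                 family_size_law = family_size_law,
                 binomial_max = as.integer(binomial_max),
                 trait_low = trait_low, trait_high = trait_high,
                 tiebreak = tiebreak),
            class = "sweep_config")
}

# Stable 31-bit seed derived from the base seed and arbitrary labels
# (polynomial rolling hash over the label characters, modulo 2^31 - 1).
derive_seed <- function(base_seed, ...) {
  m <- 2147483647
  h <- as.double(base_seed) %% m
  for (part in list(...)) {
    for (ch in utf8ToInt(paste0("|", as.character(part)))) {
      h <- (h * 131 + ch) %% m
    }
  }
  as.integer(h)
}

#' Run a fertility sweep
#'
#' For every fertility level and replicate, generates one kin network and
#' one trait vector, then completes an independent copy with each requested
#' friend-choice algorithm (paired design: identical kin and traits across
#' algorithms within a replicate), and records the friend ratio and the
#' clustering coefficient variants of each completed network.
#'
#' @param config A [sweep_config()].
#' @param progress Emit a `message()` per fertility level.
#' @return A data frame of class `sweep_result`, one row per
#'   (fertility level, replicate, algorithm): columns `fertility`,
#'   `replicate`, `algorithm`, `lambda`, `chi_nu_nsq`, `chi_nu_n`,
#'   `chi_local`, `n`, `nu`, `seed` (the fill seed of that run).  The
#'   generating configuration is attached as attribute `"config"`.
#' @export
run_sweep <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  rows <- vector("list",
                 length(config$fertility_grid) * config$replicates *
                   length(config$algorithms))
  k <- 0L
  for (li in seq_along(config$fertility_grid)) {
    fert <- config$fertility_grid[li]
    if (progress)
      message(sprintf("fertility level %d/%d (%.3f)", li,
                      length(config$fertility_grid), fert))
    for (r in seq_len(config$replicates)) {
      kin <- generate_pedigree(pedigree_params(
        n_egos = config$n, fertility = fert,
        family_size_law = config$family_size_law,
        binomial_max = config$binomial_max,
        seed = derive_seed(config$base_seed, "kin", li, r)))
      kin <- assign_traits(kin, config$trait_low, config$trait_high,
                           seed = derive_seed(config$base_seed, "trait",
                                              li, r))
      base_net <- social_network(kin, config$nu)
      for (alg in config$algorithms) {
        run_seed <- derive_seed(config$base_seed, "fill", li, r, alg)
        filled <- fill_friendships(base_net, alg,
                                   params = config$cost_params,
                                   tiebreak = config$tiebreak,
                                   seed = run_seed)
        k <- k + 1L
        rows[[k]] <- cbind(data.frame(fertility = fert, replicate = r,
                                      algorithm = alg),
                           network_summary(filled),
                           data.frame(seed = run_seed))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("sweep_result", class(out))
  out
}

#' Write sweep records as a metrics CSV
#'
#' Plain `write.csv` without row names; a rerun of the same configuration
#' and seed produces a byte-identical file.
#'
#' @param records A `sweep_result` (or compatible data frame).
#' @param path Output path.
#' @export
write_metrics_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Detect a u-shaped clustering transition in sweep records
#'
#' Bins the records of one algorithm by friend ratio into `bins`
#' equal-width bins over the realised range, averages the chosen clustering
#' statistic per bin, and tests whether the curve falls and then rises: the
#' minimising bin must be interior, and the first and last bin means must
#' each exceed the trough mean by more than two pooled standard errors.
#'
#' @param records Sweep records for a *single* algorithm.
#' @param value Column holding the clustering statistic
#'   (default `"chi_local"`).
#' @param bins Number of equal-width friend-ratio bins (default 10).
#' @return A list: `is_ushaped` (logical), `trough_lambda` (centre of the
#'   minimising bin), and `bin_stats` (data frame with per-bin `lambda_mid`,
#'   `mean`, `se`, `n_obs`).
#' @export
detect_ushape <- function(records, value = "chi_local", bins = 10L) {
  records <- as.data.frame(records)
  stopifnot(value %in% names(records), "lambda" %in% names(records))
  if ("algorithm" %in% names(records) &&
      length(unique(records$algorithm)) > 1L)
    stop("detect_ushape expects records of a single algorithm")
  stats <- bin_lambda(records, value, bins)
  if (nrow(stats) < 5L)
    stop("need at least 5 non-empty friend-ratio bins, got ", nrow(stats))
  trough <- which.min(stats$mean)
  interior <- trough > 1L && trough < nrow(stats)
  margin_ok <- FALSE
  if (interior) {
    lo <- stats[1L, ]
    hi <- stats[nrow(stats), ]
    tr <- stats[trough, ]
    margin <- function(a, b) {
      (a$mean - b$mean) > 2 * sqrt(a$se^2 + b$se^2)
    }
    margin_ok <- margin(lo, tr) && margin(hi, tr)
  }
  list(is_ushaped = interior && margin_ok,
       trough_lambda = stats$lambda_mid[trough],
       bin_stats = stats)
}

# Equal-width lambda binning with per-bin mean/se of a statistic.
# Singleton bins get se = 0 (no within-bin dispersion estimate).
bin_lambda <- function(records, value, bins, breaks = NULL) {
  lam <- records$lambda
  rng <- if (is.null(breaks)) range(lam) else range(breaks)
  if (diff(rng) == 0) {
    idx <- rep(1L, length(lam))
    mids <- rng[1]
  } else {
    brk <- if (is.null(breaks))
      seq(rng[1], rng[2], length.out = bins + 1L) else breaks
    idx <- findInterval(lam, brk, rightmost.closed = TRUE,
                        all.inside = TRUE)
    mids <- (brk[-1] + brk[-length(brk)]) / 2
  }
  occupied <- sort(unique(idx))
  stats <- do.call(rbind, lapply(occupied, function(b) {
    v <- records[[value]][idx == b]
    s <- if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
    data.frame(bin = b, lambda_mid = mids[b], mean = mean(v), se = s,
               n_obs = length(v))
  }))
  rownames(stats) <- NULL
  stats
}

#' Per-algorithm binned transition summary on common friend-ratio bins
#'
#' Bins the sweep records into `bins` equal-width friend-ratio bins over
#' the *pooled* realised range (so bins are directly comparable across
#' algorithms) and returns per-(algorithm, bin) statistics.
#'
#' @param result A `sweep_result`.
#' @param value Clustering column to summarise (default `"chi_local"`).
#' @param bins Number of bins.
#' @return Data frame with columns `algorithm`, `bin`, `lambda_mid`,
#'   `mean`, `se`, `n_obs`; only non-empty bins appear.
#' @export
transition_summary <- function(result, value = "chi_local", bins = 10L) {
  df <- as.data.frame(result)
  if (nrow(df) == 0L) stop("empty sweep result")
  rng <- range(df$lambda)
  breaks <- if (diff(rng) == 0) NULL else
    seq(rng[1], rng[2], length.out = bins + 1L)
  out <- do.call(rbind, lapply(split(df, df$algorithm), function(d) {
    s <- bin_lambda(d, value, bins, breaks = breaks)
    s$algorithm <- d$algorithm[1L]
    s[c("algorithm", "bin", "lambda_mid", "mean", "se", "n_obs")]
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of friend-ratio bins where distance weighting lifts clustering
#'
#' For sweep records containing both the `"weighted"` and `"homophily"`
#' algorithms run under the paired design (same kin network and traits per
#' replicate), computes the per-replicate difference in the clustering
#' statistic (weighted minus homophily), bins the pairs by their mean
#' friend ratio, and returns the fraction of non-empty bins whose mean
#' paired difference is non-negative.  Values above 0.5 indicate the
#' distance-weighted curve sits at or above the pure-homophily curve in a
#' majority of bins.
#'
#' @param result A `sweep_result` including both homophilic algorithms.
#' @param value Clustering column (default `"chi_local"`).
#' @param bins Number of equal-width friend-ratio bins.
#' @return Fraction in \[0, 1\].
#' @export
paired_shift_fraction <- function(result, value = "chi_local", bins = 10L) {
  df <- as.data.frame(result)
  h <- df[df$algorithm == "homophily", ]
  w <- df[df$algorithm == "weighted", ]
  if (nrow(h) == 0L || nrow(w) == 0L)
    stop("need both 'homophily' and 'weighted' records")
  m <- merge(h, w, by = c("fertility", "replicate"),
             suffixes = c(".h", ".w"))
  lam <- (m$lambda.h + m$lambda.w) / 2
  d_chi <- m[[paste0(value, ".w")]] - m[[paste0(value, ".h")]]
  rng <- range(lam)
  idx <- if (diff(rng) == 0) rep(1L, length(lam)) else
    findInterval(lam, seq(rng[1], rng[2], length.out = bins + 1L),
                 rightmost.closed = TRUE, all.inside = TRUE)
  bin_means <- tapply(d_chi, idx, mean)
  mean(bin_means >= 0)
}

#' Plot the clustering transition
#'
#' Scatter of the clustering statistic against the friend ratio with
#' per-algorithm binned means, one colour per algorithm: orange for pure
#' homophily, green for distance-weighted homophily, blue for random
#' choice.
#'
#' @param result A non-empty `sweep_result`.
#' @param path Optional output image path (written with
#'   [ggplot2::ggsave()]); when `NULL` the ggplot object is returned
#'   without writing a file.
#' @param value Clustering column to plot (default `"chi_local"`).
#' @param bins Bins for the summary lines.
#' @return The ggplot object, invisibly when `path` is given.
#' @export
plot_transition <- function(result, path = NULL, value = "chi_local",
                            bins = 10L) {
  df <- as.data.frame(result)
  if (nrow(df) == 0L) stop("empty sweep result")
  pal <- c(homophily = "#E69F00", weighted = "#009E73", random = "#0072B2")
  lines <- transition_summary(df, value, bins)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda,
                                        y = .data[[value]],
                                        colour = .data$algorithm)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_line(data = lines,
                       ggplot2::aes(x = .data$lambda_mid, y = .data$mean),
                       linewidth = 0.9) +
    ggplot2::scale_colour_manual(values = pal) +
    ggplot2::labs(x = "friend ratio (fraction of non-kin contacts)",
                  y = "clustering coefficient", colour = "friend choice") +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}
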