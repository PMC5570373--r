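#' Factor ranges for the global sensitivity analysis
#'
#' The fifteen perturbation factors with their control values and sampling
#' ranges: glutamate number per release `G0` 500-10000, resting glutamate
#' 0-1 uM, transporter concentration 0-1 mM, six desensitisation-inhibition
#' fractions 0-1, and the receptor counts/density ranges.
#'
#' @return tibble `factor`, `control`, `min`, `max`, `integer`.
#' @export
sensitivity_ranges <- function() {
  tibble::tibble(
    factor = .factor_names,
    control = c(1500, 0.25, 0.5, 0, 0, 0, 0, 0, 0, 12, 8, 85, 3, 8, 20),
    min = c(500, 0, 0, 0, 0, 0, 0, 0, 0, 6, 4, 43, 1, 4, 15),
    max = c(10000, 1, 1, 1, 1, 1, 1, 1, 1, 18, 12, 130, 5, 12, 30),
    integer = c(FALSE, FALSE, FALSE, rep(FALSE, 6),
                TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

#' Latin hypercube design over the sensitivity factor ranges
#'
#' Stratified uniform sampling: each factor column has exactly one sample in
#' each of `n` equal-probability bins of its range; integer factors are
#' rounded after scaling.
#'
#' @param n number of design rows (>= 2).
#' @param seed RNG seed (design is reproducible for a fixed seed).
#' @param ranges a tibble as from [sensitivity_ranges()].
#' @return tibble with one column per factor and `n` rows.
#' @export
#' @examples
#' lhs_design(5, seed = 1)
lhs_design <- function(n, seed = 1, ranges = sensitivity_ranges()) {
  if (n < 2) stop("LHS design needs n >= 2", call. = FALSE)
  set.seed(seed)
  u <- lhs::randomLHS(n, nrow(ranges))
  x <- sweep(u, 2, ranges$max - ranges$min, "*")
  x <- sweep(x, 2, ranges$min, "+")
  for (j in which(ranges$integer)) x[, j] <- round(x[, j])
  colnames(x) <- ranges$factor
  tibble::as_tibble(x)
}

#' Partial rank correlation coefficients
#'
#' For each (factor, output) pair: rank-transform, partial out all other
#' factors by linear residualisation on the ranks, and correlate the
#' residuals.  p-values use the t approximation with
#' `df = n - 2 - (k - 1)` for `k` factors.  Constant output columns are
#' flagged (`NA`) rather than computed.
#'
#' @param x design matrix / data frame (n rows, k factors).
#' @param y outputs (n rows, m outputs); a vector is treated as one output.
#' @param sig_prcc,sig_p significance mask thresholds.
#' @return A `sensitivity_result` tibble: `factor`, `output`, `prcc`, `p`,
#'   `significant`.
#' @export
prcc <- function(x, y, sig_prcc = 0.5, sig_p = 0.05) {
  x <- as.matrix(x)
  if (is.null(dim(y))) y <- matrix(y, ncol = 1,
                                   dimnames = list(NULL, "y"))
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y rows are not aligned", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < k + 3)
    stop("PRCC needs more rows than factors (n >= k + 3; got n = ", n,
         ", k = ", k, ")", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(k))
  if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(ncol(y)))
  rx <- apply(x, 2, rank)
  qrx <- qr(cbind(1, rx))
  if (qrx$rank < k + 1) {
    bad <- colnames(x)[qrx$pivot[-seq_len(qrx$rank)] - 1]
    stop("rank-deficient design; collinear factor(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df <- n - 2 - (k - 1)
  rows <- list()
  for (j in seq_len(ncol(y))) {
    yy <- y[, j]
    if (sd(yy) == 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        factor = colnames(x), output = colnames(y)[j],
        prcc = NA_real_, p = NA_real_, significant = FALSE)
      next
    }
    ry <- rank(yy)
    # precision-matrix route on the rank correlation matrix
    cm <- cor(cbind(ry, rx))
    om <- solve(cm)
    r <- -om[1, -1] / sqrt(om[1, 1] * diag(om)[-1])
    tstat <- r * sqrt(df / pmax(1 - r^2, 1e-15))
    pv <- 2 * pt(-abs(tstat), df)
    rows[[length(rows) + 1]] <- tibble::tibble(
      factor = colnames(x), output = colnames(y)[j],
      prcc = unname(r), p = unname(pv),
      significant = abs(r) > sig_prcc & pv < sig_p)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sensitivity_result", class(out))
  out
}

#' Global sensitivity experiment (LHS + PRCC) on the full model
#'
#' Runs the whole simulator for each design row under the chosen stimulation
#' pattern, computes the eight summary outputs and their PRCCs against the
#' fifteen factors.  Rows whose simulation fails are recorded and excluded.
#'
#' @param protocol `"lfs"` or `"hfs"` (or a `spine_protocol`).
#' @param n design size.
#' @param seed design seed.
#' @param config a [spine_config()].
#' @param train_s stimulus train length in seconds.
#' @param progress print per-row progress.
#' @return A list of class `sensitivity_experiment`: `design`, `outputs`,
#'   `prcc` (a `sensitivity_result`), `failed` (row indices), `protocol`.
#' @export
sensitivity_experiment <- function(protocol = c("lfs", "hfs"), n = 200,
                                   seed = 1, config = spine_config(),
                                   train_s = config$protocol$train_s,
                                   progress = FALSE) {
  if (is.character(protocol)) {
    protocol <- match.arg(protocol)
    proto <- make_train(if (protocol == "lfs") config$protocol$lfs_hz
                        else config$protocol$hfs_hz,
                        duration_s = train_s,
                        tail_ms = config$protocol$tail_ms)
  } else proto <- protocol
  design <- lhs_design(n, seed)
  outs <- vector("list", n)
  failed <- integer(0)
  out_names <- c("ca_by_snr2a", "ca_by_snr2b", "ca_by_pnr2b", "ca_by_enr2b",
                 "ca_peak_spine", "ca_peak_shaft", "v_peak_spine", "v_peak_shaft")
  for (i in seq_len(n)) {
    pert <- control_perturbation()
    for (f in names(design)) pert <- .apply_factor(pert, f, design[[f]][i])
    res <- tryCatch({
      sim <- run_simulation(proto, pert, config, keep_occupancies = FALSE)
      s <- summarize_simulation(sim)
      setNames(s$value[match(out_names, s$output)], out_names)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, i)
      outs[[i]] <- setNames(rep(NA_real_, length(out_names)), out_names)
    } else outs[[i]] <- res
    if (progress && i %% 10 == 0) message("row ", i, "/", n)
  }
  y <- do.call(rbind, outs)
  keep <- setdiff(seq_len(n), failed)
  pr <- prcc(design[keep, ], y[keep, , drop = FALSE])
  structure(list(design = design, outputs = tibble::as_tibble(y),
                 prcc = pr, failed = failed, protocol = proto,
                 n_used = length(keep)),
            class = "sensitivity_experiment")
}

#' @export
print.sensitivity_experiment <- function(x, ...) {
  cat("<sensitivity_experiment> ", x$protocol$label, ", n = ",
      nrow(x$design), " (", length(x$failed), " failed)\n", sep = "")
  sig <- dplyr::filter(x$prcc, .data$significant)
  cat(" ", nrow(sig), "significant factor-output pairs (|PRCC| > 0.5, p < 0.05)\n")
  invisible(x)
}

#' Heat-map style PRCC table
#'
#' Wide factor-by-output table of PRCC values with non-significant entries
#' masked to `NA`, matching the usual heat-map layout.
#'
#' @param result a `sensitivity_result` or `sensitivity_experiment`.
#' @param masked mask non-significant values.
#' @export
prcc_table <- function(result, masked = TRUE) {
  pr <- if (inherits(result, "sensitivity_experiment")) result$prcc else result
  pr <- dplyr::mutate(pr, shown = ifelse(!masked | .data$significant,
                                         .data$prcc, NA_real_))
  tidyr::pivot_wider(pr[, c("factor", "output", "shown")],
                     names_from = "output", values_from = "shown")
}
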