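#' Fit a base quality score recalibration model
#'
#' The package's central model-fitting function: counts covariates over
#' the (optionally masked) reference with [count_covariates()] and derives
#' the hierarchical recalibration deltas with [compute_deltas()]. The
#' returned object supports the usual modelling verbs: `coef()` returns
#' the delta decomposition, `predict()` recalibrates a read set,
#' `residuals()` gives per-cell leftover miscalibration after the delta
#' chain, and `plot()` draws the per-quality cycle and dinucleotide delta
#' surfaces.
#'
#' @param reads an `aligned_reads` object (or SAM path).
#' @param ref a `spike_ref`.
#' @param mask optional exclusion site set (data frame `id`, `pos`) such
#'   as the output of [read_site_vcf()]; typically the non-high-purity
#'   bases from [classify_bases()] plus any known variants.
#' @param min_observations minimum observations for a delta cell
#'   (default 100).
#' @return An object of class `bqsr` with elements `table`
#'   (the `recal_table`), `deltas` (the `recal_deltas`) and `call`.
#' @examples
#' ref <- generate_reference(2, c(300, 400), vector_len = 0, seed = 1)
#' model <- error_model(read_len = 50, q_levels = 30)
#' reads <- simulate_reads(ref, 200, model, seed = 2)
#' fit <- bqsr(reads, ref)
#' coef(fit)$global
#' recal <- predict(fit, reads)
#' @export
bqsr <- function(reads, ref, mask = NULL, min_observations = 100) {
  table <- count_covariates(reads, ref, mask = mask)
  deltas <- compute_deltas(table, min_observations = min_observations)
  structure(list(
    table = table, deltas = deltas,
    min_observations = min_observations,
    n_observations = sum(table$observations),
    n_errors = sum(table$errors),
    call = match.call()
  ), class = "bqsr")
}

#' @export
print.bqsr <- function(x, ...) {
  cat("Base quality score recalibration fit\n")
  cat(sprintf("  observations: %.0f   errors: %.0f (empirical Q%.2f)\n",
              x$n_observations, x$n_errors, x$deltas$empirical_all))
  cat(sprintf("  mean reported quality: %.2f   global delta: %+.3f\n",
              x$deltas$mean_reported, x$deltas$global))
  invisible(x)
}

#' @export
summary.bqsr <- function(object, ...) {
  d <- object$deltas
  din <- colMeans(d$dinuc, na.rm = TRUE)
  cyc <- colMeans(d$cycle, na.rm = TRUE)
  out <- list(
    n_observations = object$n_observations,
    n_errors = object$n_errors,
    empirical_all = d$empirical_all,
    mean_reported = d$mean_reported,
    global = d$global,
    qs = d$qs,
    dinuc_mean = din[order(din)],
    cycle_range = if (any(is.finite(cyc))) range(cyc, na.rm = TRUE) else c(NA_real_, NA_real_)
  )
  class(out) <- "summary.bqsr"
  out
}

#' @export
print.summary.bqsr <- function(x, ...) {
  cat("BQSR summary\n")
  cat(sprintf("  %.0f observations, %.0f errors; empirical Q%.2f vs reported %.2f (global %+.3f)\n",
              x$n_observations, x$n_errors, x$empirical_all, x$mean_reported, x$global))
  cat("  mean dinucleotide deltas (worst first):\n")
  print(round(x$dinuc_mean, 3))
  cat(sprintf("  cycle delta range: [%+.3f, %+.3f]\n",
              x$cycle_range[1], x$cycle_range[2]))
  invisible(x)
}

#' @export
coef.bqsr <- function(object, ...) object$deltas

#' @rdname bqsr
#' @param object a fitted `bqsr` object.
#' @param newdata an `aligned_reads` object to recalibrate.
#' @param ... unused.
#' @export
predict.bqsr <- function(object, newdata, ...) {
  recalibrate_reads(newdata, object$deltas)
}

#' @export
#' @rdname bqsr
#' @param min_observations for `residuals()`: smallest per-cell count at
#'   which a full three-way cell's empirical quality is stable enough to
#'   be a meaningful residual (default 1000; full cells are far sparser
#'   than the marginals the deltas are fitted on).
residuals.bqsr <- function(object, min_observations = 1000, ...) {
  t <- object$table
  keep <- t$observations >= min_observations & t$dinuc != "NA"
  t <- t[keep, , drop = FALSE]
  emp <- empirical_quality(t$errors, t$observations)
  pred <- t$q + delta_lookup(object$deltas, as.character(t$q), t$cycle, t$dinuc)
  structure(emp - pred, names = paste(t$q, t$cycle, t$dinuc, sep = ":"))
}

#' @export
plot.bqsr <- function(x, ...) {
  d <- x$deltas
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panel <- function(z, xv, xlab, main, labels = NULL) {
    if (!any(is.finite(z))) return(invisible())
    # y axis needs >= 2 distinct quality levels for image(); pad if not
    yv <- as.integer(rownames(z))
    if (length(yv) == 1L) {
      yv <- c(yv, yv + 1L)
      z <- rbind(z, NA)
    }
    graphics::image(
      x = xv, y = yv, z = t(z), zlim = range(z, finite = TRUE),
      xlab = xlab, ylab = "reported quality", main = main,
      xaxt = if (is.null(labels)) "s" else "n", ...
    )
    if (!is.null(labels)) {
      graphics::axis(1, at = xv, labels = labels, las = 2, cex.axis = 0.6)
    }
  }
  panel(d$cycle, as.integer(colnames(d$cycle)), "machine cycle", "cycle deltas")
  panel(d$dinuc, seq_len(16), "dinucleotide", "dinucleotide deltas", DINUCS)
  invisible(x)
}
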