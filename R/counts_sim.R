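#' Count-level simulation of recalibration tables
#'
#' Draws recalibration tables directly from the generative error model
#' without materialising reads, for experiment scales (for example
#' millions of 100-bp reads) where per-read simulation is unnecessary:
#' every covariate cell's observation count is Poisson with mean equal to
#' its expectation under uniform read placement, and its error count is
#' binomial with the model's cell error probability (averaging the
#' per-site SSE multipliers over the positions contributing to the cell).
#'
#' Position groups partition the *visible* reference bases: each group
#' yields one table counting only its positions (the complement of a
#' group acting as a mask). Read fractions split the reads instead, so
#' nested designs are obtained by summing sub-tables: e.g. the table of a
#' 10% position subset plus the table of the remaining 90% equals a full
#' table counted from the same reads.
#'
#' Approximations relative to [simulate_reads()]: read placement edge
#' effects are ignored (every position has the same expected coverage),
#' observation counts are Poisson rather than multinomial, and the few
#' positions at record boundaries without a dinucleotide context are
#' dropped. Cycle-1 observations (no previous sequenced base) are
#' emitted with dinucleotide `"NA"`.
#'
#' @param ref a `spike_ref`.
#' @param model an `error_model`.
#' @param n_reads total number of reads represented.
#' @param seed integer seed.
#' @param position_groups named list of site sets (data frames `id`,
#'   `pos`), each a visible-position group.
#' @param read_fractions named numeric vector of read fractions (summing
#'   to at most 1); default a single full-read fraction.
#' @param read_group read group label for the tables.
#' @return named list of `recal_table` objects, one per position group x
#'   read fraction (names `group` or `group.fraction`).
#' @export
simulate_count_tables <- function(ref, model, n_reads, seed, position_groups,
                                  read_fractions = c(all = 1),
                                  read_group = "RG1") {
  n_reads <- check_count(n_reads, "n_reads")
  stopifnot(is.list(position_groups), !is.null(names(position_groups)))
  if (any(read_fractions <= 0) || sum(read_fractions) > 1 + 1e-9) {
    stop_invalid("read_fractions must be positive and sum to at most 1")
  }
  if (is.null(names(read_fractions))) names(read_fractions) <- seq_along(read_fractions)
  fl <- ref_flat(ref)
  L <- model$read_len
  G <- sum(fl$lens)
  rate0 <- n_reads / (2 * G) # expected obs per (position, strand, cycle)
  site <- site_effects(ref, model, seed)
  mult <- 10^(-site / 10) # error-rate multiplier per (position, strand)

  # per-group dinucleotide composition and mean SSE multiplier
  group_stats <- lapply(position_groups, function(g) {
    ri <- match(g$id, fl$ids)
    if (anyNA(ri)) stop_data("position group references unknown ids")
    gi <- fl$offset[ri] + g$pos + 1L
    cur <- fl$codes[gi]
    first <- g$pos == 0L
    last <- g$pos == fl$lens[ri] - 1L
    prev <- ifelse(first, NA_integer_, fl$codes[pmax(gi - 1L, 1L)])
    nxt <- ifelse(last, NA_integer_, fl$codes[pmin(gi + 1L, G)])
    d_fwd <- (prev - 1L) * 4L + cur
    d_rev <- (comp_int(nxt) - 1L) * 4L + comp_int(cur)
    d <- c(d_fwd, d_rev)
    m <- c(mult[cbind(gi, 1L)], mult[cbind(gi, 2L)])
    ok <- !is.na(d)
    n_inst <- tabulate(d[ok], nbins = 16L)
    m_sum <- vapply(1:16, function(k) sum(m[ok][d[ok] == k]), numeric(1))
    list(n_inst = n_inst, m_sum = m_sum, n_all = 2L * nrow(g),
         m_all = sum(m))
  })

  qs <- model$q_levels
  pq <- model$q_prob
  qo <- unname(model$qs_offset)[qs - 1L]
  co <- model$cycle_offset
  dino <- unname(model$dinuc_offset)

  out <- list()
  with_seed(seed + 1L, {
    for (gn in names(position_groups)) {
      st <- group_stats[[gn]]
      mbar <- ifelse(st$n_inst > 0, st$m_sum / st$n_inst, 1)
      # dinucleotide-resolved cells for cycles 2..L
      grid <- expand.grid(qi = seq_along(qs), cyc = 2:L, d = 1:16)
      grid <- grid[st$n_inst[grid$d] > 0, , drop = FALSE]
      e_obs <- rate0 * pq[grid$qi] * st$n_inst[grid$d]
      p_err <- pmin(model$p_max,
                    10^(-(qs[grid$qi] + qo[grid$qi] + co[grid$cyc] + dino[grid$d]) / 10) *
                      mbar[grid$d])
      # cycle-1 cells, no dinucleotide context
      g1 <- expand.grid(qi = seq_along(qs), cyc = 1L, d = NA_integer_)
      e1 <- rate0 * pq[g1$qi] * st$n_all
      p1 <- pmin(model$p_max,
                 10^(-(qs[g1$qi] + qo[g1$qi] + co[1L]) / 10) *
                   (st$m_all / max(st$n_all, 1L)))
      for (fn in names(read_fractions)) {
        fr <- read_fractions[[fn]]
        obs <- stats::rpois(nrow(grid), fr * e_obs)
        err <- stats::rbinom(nrow(grid), obs, p_err)
        obs1 <- stats::rpois(nrow(g1), fr * e1)
        err1 <- stats::rbinom(nrow(g1), obs1, p1)
        tab <- data.frame(
          read_group = read_group,
          q = c(qs[grid$qi], qs[g1$qi]),
          cycle = as.integer(c(grid$cyc, g1$cyc)),
          dinuc = c(DINUCS[grid$d], rep("NA", nrow(g1))),
          observations = as.numeric(c(obs, obs1)),
          errors = as.numeric(c(err, err1)),
          stringsAsFactors = FALSE
        )
        tab <- tab[tab$observations > 0, , drop = FALSE]
        tab <- tab[order(tab$q, tab$cycle, tab$dinuc), ]
        rownames(tab) <- NULL
        nm <- if (length(read_fractions) == 1L) gn else paste(gn, fn, sep = ".")
        out[[nm]] <- structure(tab, class = c("recal_table", "data.frame"))
      }
    }
  })
  out
}
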