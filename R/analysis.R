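#' Cell-assembly membership from evaluation rasters
#'
#' A neuron is *active* in a trial if it fires at least once during that
#' trial.  Under the default `"trials"` criterion, a neuron belongs to the
#' word's cell assembly if it is active in at least `min_count` of the six
#' evaluation trials (three auditory-port, three articulatory-port).  The
#' alternative `"spikes"` criterion counts total spikes across the six
#' trials instead.
#'
#' @param rasters List of exactly 6 `spike_raster` objects for one word.
#' @param criterion `"trials"` (default) or `"spikes"`.
#' @param min_count Membership threshold (default 4).
#' @return Logical vector over all excitatory units (class
#'   `ca_membership`, with `areas` and `n_exc` attributes).
#' @export
ca_membership <- function(rasters, criterion = c("trials", "spikes"),
                          min_count = 4) {
  criterion <- match.arg(criterion)
  if (length(rasters) != 6L)
    stop("ca_membership: exactly 6 evaluation rasters are required, got ",
         length(rasters))
  per_trial <- vapply(rasters, function(r) {
    stopifnot(inherits(r, "spike_raster"))
    colSums(r)
  }, numeric(ncol(rasters[[1]])))
  member <- if (criterion == "trials") {
    rowSums(per_trial > 0) >= min_count
  } else {
    rowSums(per_trial) >= min_count
  }
  structure(member, class = "ca_membership",
            areas = attr(rasters[[1]], "areas"),
            n_exc = attr(rasters[[1]], "n_exc"))
}

#' Per-area cell-assembly neuron counts
#'
#' @param membership A [ca_membership()] vector.
#' @return Named integer vector: number of CA neurons per area.
#' @export
ca_counts <- function(membership) {
  areas <- attr(membership, "areas")
  ne <- attr(membership, "n_exc")
  area_of <- rep(seq_along(areas), each = ne)
  counts <- tabulate(area_of[as.logical(membership)], nbins = length(areas))
  setNames(as.integer(counts), areas)
}

#' Evaluate a trained network over a pattern set
#'
#' Runs the full 6-trial evaluation for every word and maps the cell
#' assemblies.
#'
#' @param net Trained network.
#' @param patterns Pattern list.
#' @param cfg An [evaluation_config()].
#' @param network_id Identifier recorded in the output rows.
#' @return A cell-assembly table: data frame with columns `network_id`,
#'   `word_id`, `category`, `area`, `ca_count`.
#' @export
evaluate_network <- function(net, patterns, cfg = evaluation_config(),
                             network_id = 1L) {
  rows <- lapply(patterns, function(pat) {
    counts <- ca_counts(ca_membership(evaluate_word(net, pat, cfg)))
    data.frame(network_id = network_id, word_id = pat$word_id,
               category = pat$category, area = names(counts),
               ca_count = as.integer(counts), row.names = NULL)
  })
  ca_table(do.call(rbind, rows))
}

#' Validate a cell-assembly table
#'
#' @param x Data frame with columns `network_id`, `word_id`, `category`,
#'   `area`, `ca_count`.
#' @return `x` with class `ca_table`, after checking that counts lie in
#'   `[0, 625]` and that the `network x word x area` grid is complete.
#' @export
ca_table <- function(x) {
  need <- c("network_id", "word_id", "category", "area", "ca_count")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("ca_table: missing columns: ", paste(miss, collapse = ", "))
  if (any(x$ca_count < 0 | x$ca_count > N_EXC))
    stop("ca_table: ca_count outside [0, 625]")
  grid <- table(x$network_id, x$word_id, x$area)
  if (any(grid != 1))
    stop("ca_table: network x word x area grid is incomplete or duplicated")
  class(x) <- c("ca_table", "data.frame")
  x
}

# per-network cell means: average ca_count over words within category,
# giving the network x wordtype x area array analysed by the ANOVA
ca_cell_means <- function(table) {
  agg <- stats::aggregate(ca_count ~ network_id + category + area,
                          data = table, FUN = mean)
  nets <- sort(unique(agg$network_id))
  cats <- sort(unique(agg$category))
  areas <- unique(table$area)
  y <- array(NA_real_, dim = c(length(nets), length(cats), length(areas)),
             dimnames = list(network = as.character(nets), wordtype = cats,
                             area = areas))
  idx <- cbind(match(agg$network_id, nets), match(agg$category, cats),
               match(agg$area, areas))
  y[idx] <- agg$ca_count
  if (anyNA(y))
    stop("rm_anova: unbalanced design (missing network x wordtype x area ",
         "cells)")
  y
}

#' Two-way repeated-measures ANOVA on cell-assembly counts
#'
#' Within-subject (network) ANOVA with factors WordType (2 levels) and
#' Area (12 levels) on the per-network mean CA counts, using the standard
#' repeated-measures sums-of-squares decomposition: each effect is tested
#' against its own effect-by-subject interaction.  No sphericity
#' correction is applied.
#'
#' @param table A [ca_table()] (2 or more networks).
#' @return An object of class `anova_result`: a list with the effects
#'   data frame (`effect`, `df1`, `df2`, `ss`, `F`, `p`) and the cell
#'   means array.
#' @export
rm_anova <- function(table) {
  y <- ca_cell_means(table)
  ns <- dim(y)[1]; na <- dim(y)[2]; nb <- dim(y)[3]
  if (ns < 2) stop("rm_anova: at least 2 networks are required")
  m <- mean(y)
  m_s <- apply(y, 1, mean)
  m_a <- apply(y, 2, mean)
  m_b <- apply(y, 3, mean)
  m_sa <- apply(y, c(1, 2), mean)
  m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)

  ss_a <- ns * nb * sum((m_a - m)^2)
  ss_as <- nb * sum((m_sa - outer(m_s, rep(1, na)) -
                       outer(rep(1, ns), m_a) + m)^2)
  ss_b <- ns * na * sum((m_b - m)^2)
  ss_bs <- na * sum((m_sb - outer(m_s, rep(1, nb)) -
                       outer(rep(1, ns), m_b) + m)^2)
  ss_ab <- ns * sum((m_ab - outer(m_a, rep(1, nb)) -
                       outer(rep(1, na), m_b) + m)^2)
  resid <- y
  for (s in seq_len(ns)) for (a in seq_len(na)) for (b in seq_len(nb))
    resid[s, a, b] <- y[s, a, b] - m_sa[s, a] - m_sb[s, b] - m_ab[a, b] +
      m_s[s] + m_a[a] + m_b[b] - m
  ss_abs <- sum(resid^2)

  df <- function(k) k - 1
  eff <- data.frame(
    effect = c("wordtype", "area", "wordtype:area"),
    df1 = c(df(na), df(nb), df(na) * df(nb)),
    df2 = c(df(na) * df(ns), df(nb) * df(ns), df(na) * df(nb) * df(ns)),
    ss = c(ss_a, ss_b, ss_ab))
  err_ss <- c(ss_as, ss_bs, ss_abs)
  eff$F <- (eff$ss / eff$df1) / (err_ss / eff$df2)
  eff$F[err_ss == 0 & eff$ss == 0] <- 0
  eff$p <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  structure(list(effects = eff, cell_means = y), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  e <- x$effects
  for (i in seq_len(nrow(e)))
    cat(sprintf("%-14s F(%d, %d) = %.3f, p = %.4g\n", e$effect[i],
                e$df1[i], e$df2[i], e$F[i], e$p[i]))
  invisible(x)
}

#' Per-area post-hoc comparison of word types
#'
#' Following a significant WordType-by-Area interaction, compares action
#' against object CA counts within each area by a paired comparison
#' across networks (with two word-type levels the Tukey contrast reduces
#' to a paired t test), Bonferroni-corrected over the number of areas:
#' significance is declared at `p < alpha / n_comparisons`.
#'
#' @param table A [ca_table()].
#' @param alpha Family-wise level (default 0.05).
#' @param n_comparisons Number of comparisons corrected for (default 12
#'   areas; `0.05 / 12` gives the critical level 0.0042).
#' @return List with the per-area results data frame (`area`,
#'   `mean_action`, `mean_object`, `statistic`, `p`, `significant`) and
#'   `critical_p`.
#' @export
posthoc_wordtype_by_area <- function(table, alpha = 0.05,
                                     n_comparisons = 12) {
  y <- ca_cell_means(table)
  crit <- alpha / n_comparisons
  areas <- dimnames(y)$area
  res <- lapply(areas, function(a) {
    act <- y[, "action", a]
    obj <- y[, "object", a]
    dd <- act - obj
    if (all(dd == 0)) {
      stat <- 0; p <- 1
    } else if (stats::sd(dd) == 0) {
      stat <- sign(mean(dd)) * Inf; p <- 0
    } else {
      tt <- stats::t.test(act, obj, paired = TRUE)
      stat <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(area = a, mean_action = mean(act), mean_object = mean(obj),
               statistic = stat, p = p, significant = p < crit)
  })
  list(table = do.call(rbind, res), critical_p = crit)
}

#' Per-area activation time course of a raster
#'
#' @param raster A `spike_raster`.
#' @return Integer matrix `steps x areas` of spike counts, with the
#'   stimulation window (if any) in the `stim_window` attribute.
#' @export
time_course <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  areas <- attr(raster, "areas")
  ne <- attr(raster, "n_exc")
  area_of <- rep(seq_along(areas), each = ne)
  tc <- t(rowsum(t(unclass(raster)), group = area_of))
  colnames(tc) <- areas
  structure(tc, stim_window = attr(raster, "stim_window"))
}
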