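# Strand-break detection, SSB/DSB cluster classification and yield
# computation.
#
# A nucleotide breaks in a given event when the cumulative energy scored
# in its phosphate or its deoxyribose bead strictly exceeds that bead's
# threshold. Breaks of one event and segment are then clustered with a
# 10-bp window (modular distance on circular plasmids) and each cluster
# is reported once at its most complex class:
#   SSB < SSB+ < 2SSB < DSB < DSB+ < DSB++
# SSB: isolated break. SSB+: >= 2 same-strand breaks within the window.
# 2SSB: single-strand lesions on opposite strands farther apart than the
# window. DSB: one opposite-strand pair within the window. DSB+: a DSB
# with >= 1 extra break in its cluster. DSB++: >= 2 DSBs in one cluster.

.break_classes <- c("SSB", "SSBp", "2SSB", "DSB", "DSBp", "DSBpp")

#' Detect strand breaks from a score table
#'
#' A break occurs at a nucleotide (per event) when the energy accumulated
#' in its phosphate bead or in its deoxyribose bead strictly exceeds the
#' bead's threshold; base beads are never break sites.
#'
#' @param score_table a `score_table` from [score_events()].
#' @param beads the bead table the scores refer to.
#' @return data.frame of break records: `event_id`, `segment_id`,
#'   `strand`, `nucleotide_index`, `trigger` ("phosphate",
#'   "deoxyribose" or "both"); at most one row per (event, segment,
#'   strand, nucleotide).
#' @export
find_breaks <- function(score_table, beads) {
  sc <- data.table::as.data.table(score_table$scores)
  bd <- data.table::as.data.table(beads)[
    , .(bead_id, segment_id, strand, nucleotide_index, moiety,
        threshold_eV)]
  if (nrow(sc) == 0)
    return(data.frame(event_id = integer(), segment_id = integer(),
                      strand = integer(), nucleotide_index = integer(),
                      trigger = character()))
  j <- bd[sc, on = "bead_id", nomatch = NULL]
  j <- j[!is.na(threshold_eV) & energy > threshold_eV]
  if (nrow(j) == 0)
    return(data.frame(event_id = integer(), segment_id = integer(),
                      strand = integer(), nucleotide_index = integer(),
                      trigger = character()))
  br <- j[, .(trigger = if (data.table::uniqueN(moiety) > 1) "both"
              else moiety[1]),
          by = .(event_id, segment_id, strand, nucleotide_index)]
  data.table::setorder(br, event_id, segment_id, strand, nucleotide_index)
  as.data.frame(br)
}

# base-pair separation, modular for circular topologies
.bp_dist <- function(i, j, topology, n_bp) {
  d <- abs(i - j)
  if (topology == "circular") pmin(d, n_bp - d) else d
}

#' Classify the strand breaks of one event and segment
#'
#' Breaks are grouped into clusters by single-linkage with the `max_sep`
#' window (two breaks belong together when their base-pair separation is
#' `<= max_sep`, on either strand). Within a cluster, opposite-strand
#' pairs within the window are matched greedily, closest pair first
#' (global minimum distance, ties broken by lower strand-0 position then
#' lower strand-1 position), each break used at most once; the number of
#' matched pairs and leftover breaks fixes the cluster class. Isolated
#' single-strand clusters on opposite strands are then paired (nearest
#' first) into 2SSB lesions.
#'
#' @param breaks data.frame with columns `strand` and `nucleotide_index`
#'   (one event, one segment; duplicates are dropped).
#' @param max_sep clustering window, bp (default 10).
#' @param topology `"linear"` or `"circular"`.
#' @param n_bp segment length in bp (required for circular topology).
#' @return named integer vector of counts over
#'   `SSB, SSBp, 2SSB, DSB, DSBp, DSBpp`.
#' @export
#' @examples
#' classify_breaks(data.frame(strand = c(0, 1),
#'                            nucleotide_index = c(100, 105)),
#'                 topology = "linear")  # one DSB
classify_breaks <- function(breaks, max_sep = 10,
                            topology = c("linear", "circular"),
                            n_bp = NULL) {
  topology <- match.arg(topology)
  if (topology == "circular" && is.null(n_bp))
    stop("circular topology requires n_bp")
  counts <- stats::setNames(integer(length(.break_classes)),
                            .break_classes)
  if (is.null(breaks) || nrow(breaks) == 0) return(counts)
  b <- unique(breaks[, c("strand", "nucleotide_index")])
  n <- nrow(b)

  # single-linkage components under the window relation
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (.bp_dist(b$nucleotide_index[i], b$nucleotide_index[j],
                   topology, n_bp) <= max_sep) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))

  single_strand_clusters <- list()
  for (rt in unique(roots)) {
    idx <- which(roots == rt)
    cl <- b[idx, , drop = FALSE]
    # greedy closest-first opposite-strand pairing
    pool <- seq_len(nrow(cl))
    n_pairs <- 0L
    repeat {
      best <- NULL
      for (ii in pool) for (jj in pool) {
        if (jj <= ii || cl$strand[ii] == cl$strand[jj]) next
        d <- .bp_dist(cl$nucleotide_index[ii], cl$nucleotide_index[jj],
                      topology, n_bp)
        if (d > max_sep) next
        i0 <- if (cl$strand[ii] < cl$strand[jj]) ii else jj
        i1 <- if (i0 == ii) jj else ii
        key <- c(d, cl$nucleotide_index[i0], cl$nucleotide_index[i1])
        if (is.null(best) || .lex_lt(key, best$key))
          best <- list(i = ii, j = jj, key = key)
      }
      if (is.null(best)) break
      n_pairs <- n_pairs + 1L
      pool <- setdiff(pool, c(best$i, best$j))
    }
    extras <- length(pool)
    if (n_pairs >= 2L) {
      counts["DSBpp"] <- counts["DSBpp"] + 1L
    } else if (n_pairs == 1L) {
      if (extras > 0) counts["DSBp"] <- counts["DSBp"] + 1L
      else counts["DSB"] <- counts["DSB"] + 1L
    } else {
      # a window-connected component with no opposite-strand pair is
      # necessarily single-strand
      single_strand_clusters[[length(single_strand_clusters) + 1L]] <-
        list(strand = cl$strand[1],
             pos = mean(cl$nucleotide_index),
             class = if (nrow(cl) >= 2) "SSBp" else "SSB")
    }
  }

  # pair single-strand clusters on opposite strands into 2SSB lesions
  if (length(single_strand_clusters)) {
    s <- vapply(single_strand_clusters, `[[`, numeric(1), "strand")
    p <- vapply(single_strand_clusters, `[[`, numeric(1), "pos")
    klass <- vapply(single_strand_clusters, `[[`, character(1), "class")
    pool <- seq_along(s)
    repeat {
      cand <- NULL
      for (ii in pool) for (jj in pool) {
        if (jj <= ii || s[ii] == s[jj]) next
        d <- .bp_dist(p[ii], p[jj], topology, n_bp)
        i0 <- if (s[ii] < s[jj]) ii else jj
        i1 <- if (i0 == ii) jj else ii
        key <- c(d, p[i0], p[i1])
        if (is.null(cand) || .lex_lt(key, cand$key))
          cand <- list(i = ii, j = jj, key = key)
      }
      if (is.null(cand)) break
      counts["2SSB"] <- counts["2SSB"] + 1L
      pool <- setdiff(pool, c(cand$i, cand$j))
    }
    for (ii in pool) counts[klass[ii]] <- counts[klass[ii]] + 1L
  }
  counts
}

# lexicographic a < b for equal-length numeric keys
.lex_lt <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

#' Tally break subtype counts over all events and segments
#'
#' @param breaks break records from [find_breaks()].
#' @param topology segment topology ("linear" or "circular").
#' @param n_bp segment length, bp.
#' @param max_sep clustering window, bp.
#' @param dose absorbed dose of the scored event set, Gy.
#' @param total_bp total base pairs in the irradiated volume.
#' @return object of class `damage_tally`: list with `counts` (named
#'   totals over the six classes), `per_event` (data.frame of per-event
#'   per-segment counts), `dose`, `total_bp`.
#' @export
tally_damage <- function(breaks, topology, n_bp, max_sep = 10,
                         dose = NA_real_, total_bp = NA_real_) {
  counts <- stats::setNames(integer(length(.break_classes)),
                            .break_classes)
  per_event <- list()
  if (nrow(breaks)) {
    grp <- split(breaks,
                 paste(breaks$event_id, breaks$segment_id, sep = "/"))
    for (g in names(grp)) {
      cc <- classify_breaks(grp[[g]], max_sep = max_sep,
                            topology = topology, n_bp = n_bp)
      counts <- counts + cc
      per_event[[g]] <- data.frame(
        event_id = grp[[g]]$event_id[1],
        segment_id = grp[[g]]$segment_id[1],
        as.list(cc))
    }
  }
  structure(list(counts = counts,
                 per_event = if (length(per_event))
                   do.call(rbind, per_event) else NULL,
                 dose = dose, total_bp = total_bp),
            class = "damage_tally")
}

#' @export
print.damage_tally <- function(x, ...) {
  cat("Damage tally:\n")
  print(x$counts)
  if (!is.na(x$dose))
    cat(sprintf("dose %.4g Gy over %.4g bp\n", x$dose, x$total_bp))
  invisible(x)
}

#' Strand-break yields per Gy per Gbp
#'
#' The SSB yield counts SSB + SSB+ + 2 x 2SSB lesions (a 2SSB is two
#' separate single-strand lesions; set `two_ssb_counts = 1` to count it
#' once); the DSB yield counts DSB + DSB+ + 2 x DSB++ (a DSB++ cluster
#' holds at least two double-strand lesions; `two_dsb_counts = 1` to
#' count it once).
#'
#' @param tally a `damage_tally` with `dose` (> 0) and `total_bp` set.
#' @param nominal_LET optional LET label carried through, keV/um.
#' @param two_ssb_counts multiplicity of a 2SSB lesion in the SSB yield.
#' @param two_dsb_counts multiplicity of a DSB++ cluster in the DSB
#'   yield.
#' @return data.frame with `ssb_yield`, `dsb_yield` (Gy^-1 Gbp^-1),
#'   `ratio` (SSB/DSB, NA when no DSB), `dose`, `nominal_LET`.
#' @export
yields <- function(tally, nominal_LET = NA_real_,
                   two_ssb_counts = 2, two_dsb_counts = 2) {
  if (is.na(tally$dose) || tally$dose <= 0) stop("dose must be positive")
  if (is.na(tally$total_bp) || tally$total_bp <= 0)
    stop("total_bp must be positive")
  cc <- tally$counts
  gbp <- tally$total_bp * 1e-9
  ssb <- (cc["SSB"] + cc["SSBp"] + two_ssb_counts * cc["2SSB"]) /
    (tally$dose * gbp)
  dsb <- (cc["DSB"] + cc["DSBp"] + two_dsb_counts * cc["DSBpp"]) /
    (tally$dose * gbp)
  data.frame(ssb_yield = unname(ssb), dsb_yield = unname(dsb),
             ratio = unname(if (dsb > 0) ssb / dsb else NA_real_),
             dose = tally$dose, nominal_LET = nominal_LET)
}

#' Mean absolute percentage error between simulated and measured values
#'
#' `mean(|(sim - exp) / exp|) * 100`.
#'
#' @param sim_values simulated values.
#' @param exp_values experimental reference values (non-zero).
#' @return mean percentage error.
#' @export
#' @examples
#' mean_percentage_error(c(2, 1), c(1, 2))  # 75
mean_percentage_error <- function(sim_values, exp_values) {
  if (length(sim_values) != length(exp_values))
    stop("sim_values and exp_values must have equal length")
  if (any(exp_values == 0))
    stop("experimental values must be non-zero")
  mean(abs((sim_values - exp_values) / exp_values)) * 100
}
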