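# Independent reference implementations (oracles) and shared fixtures.
# The oracles deliberately avoid the package's data structures and
# algorithms: classification uses igraph components plus a plain
# matrix-scan greedy pairing, scoring is an all-pairs loop, and the
# union volume has a closed-form two-sphere solution.

.fixture_env <- new.env(parent = emptyenv())

# small models reused across test files, built once
fixture_model <- function(n_bp = 20, topology = "linear",
                          form = NULL) {
  key <- paste(n_bp, topology, form %||% "", sep = "/")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- build_bdna(n_bp, topology, form)
  .fixture_env[[key]]
}

fixture_cg <- function(n_bp = 20, topology = "linear", form = NULL,
                       scoring = "hydration") {
  key <- paste("cg", n_bp, topology, form %||% "", scoring, sep = "/")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- build_cg_model(
      fixture_model(n_bp, topology, form), scoring = scoring,
      volumes = c(phosphate = 0.050, deoxyribose = 0.084, base = 0.104))
  .fixture_env[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exact union volume of two overlapping spheres (radii in Angstrom,
# centre distance d), returned in nm^3
two_sphere_union <- function(r1, r2, d) {
  if (d >= r1 + r2) {
    v <- 4 / 3 * pi * (r1^3 + r2^3)
  } else if (d <= abs(r1 - r2)) {
    v <- 4 / 3 * pi * max(r1, r2)^3
  } else {
    lens <- pi * (r1 + r2 - d)^2 *
      (d^2 + 2 * d * r2 - 3 * r2^2 + 2 * d * r1 + 6 * r1 * r2 -
         3 * r1^2) / (12 * d)
    v <- 4 / 3 * pi * (r1^3 + r2^3) - lens
  }
  v / 1000
}

# brute-force nearest-bead deposit assignment
oracle_score <- function(events, beads) {
  rows <- list()
  sr2 <- beads$scoring_radius_nm^2
  for (k in seq_len(nrow(events))) {
    d2 <- (beads$x - events$x[k])^2 + (beads$y - events$y[k])^2 +
      (beads$z - events$z[k])^2
    ok <- which(d2 <= sr2)
    if (!length(ok)) next
    o <- ok[order(d2[ok], beads$bead_id[ok])][1]
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = events$event_id[k], bead_id = beads$bead_id[o],
      energy = events$energy[k])
  }
  if (!length(rows))
    return(data.frame(event_id = integer(), bead_id = integer(),
                      energy = numeric()))
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(energy ~ event_id + bead_id, df, sum)
  agg[order(agg$event_id, agg$bead_id), , drop = FALSE]
}

lex_lt <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

# exhaustive re-implementation of the break-classification semantics:
# igraph connected components under the bp window, greedy closest-first
# opposite-strand pairing with the (distance, strand-0 position,
# strand-1 position) tie key, then nearest-first 2SSB pairing of
# leftover single-strand clusters.
oracle_classify <- function(breaks, max_sep = 10, topology = "linear",
                            n_bp = NULL) {
  classes <- c("SSB", "SSBp", "2SSB", "DSB", "DSBp", "DSBpp")
  counts <- stats::setNames(integer(6), classes)
  b <- unique(breaks[, c("strand", "nucleotide_index")])
  n <- nrow(b)
  if (n == 0) return(counts)
  dist_bp <- function(i, j) {
    d <- abs(i - j)
    if (topology == "circular") pmin(d, n_bp - d) else d
  }
  D <- outer(b$nucleotide_index, b$nucleotide_index, dist_bp)
  if (n == 1) {
    memb <- 1L
  } else {
    g <- igraph::graph_from_adjacency_matrix(D <= max_sep,
                                             mode = "undirected",
                                             diag = FALSE)
    memb <- igraph::components(g)$membership
  }

  greedy_pairs <- function(pos, str, dfun) {
    avail <- rep(TRUE, length(pos))
    np <- 0L
    repeat {
      cand <- NULL
      for (ii in seq_along(pos)) for (jj in seq_along(pos)) {
        if (!avail[ii] || !avail[jj]) next
        if (!(str[ii] == 0 && str[jj] == 1)) next
        d <- dfun(pos[ii], pos[jj])
        if (d > max_sep) next
        key <- c(d, pos[ii], pos[jj])
        if (is.null(cand) || lex_lt(key, cand$key))
          cand <- list(i = ii, j = jj, key = key)
      }
      if (is.null(cand)) break
      np <- np + 1L
      avail[c(cand$i, cand$j)] <- FALSE
    }
    list(n_pairs = np, leftover = which(avail))
  }

  ss <- list()
  for (cmp in unique(memb)) {
    idx <- which(memb == cmp)
    pos <- b$nucleotide_index[idx]
    str <- b$strand[idx]
    gp <- greedy_pairs(pos, str, dist_bp)
    if (gp$n_pairs >= 2) {
      counts["DSBpp"] <- counts["DSBpp"] + 1L
    } else if (gp$n_pairs == 1) {
      counts[if (length(gp$leftover)) "DSBp" else "DSB"] <-
        counts[if (length(gp$leftover)) "DSBp" else "DSB"] + 1L
    } else {
      ss[[length(ss) + 1L]] <- list(strand = str[1], pos = mean(pos),
                                    class = if (length(idx) >= 2)
                                      "SSBp" else "SSB")
    }
  }
  if (length(ss)) {
    s <- vapply(ss, `[[`, numeric(1), "strand")
    p <- vapply(ss, `[[`, numeric(1), "pos")
    kl <- vapply(ss, `[[`, character(1), "class")
    avail <- rep(TRUE, length(s))
    repeat {
      cand <- NULL
      for (ii in seq_along(s)) for (jj in seq_along(s)) {
        if (!avail[ii] || !avail[jj]) next
        if (!(s[ii] == 0 && s[jj] == 1)) next
        d <- dist_bp(p[ii], p[jj])
        key <- c(d, p[ii], p[jj])
        if (is.null(cand) || lex_lt(key, cand$key))
          cand <- list(i = ii, j = jj, key = key)
      }
      if (is.null(cand)) break
      counts["2SSB"] <- counts["2SSB"] + 1L
      avail[c(cand$i, cand$j)] <- FALSE
    }
    for (ii in which(avail)) counts[kl[ii]] <- counts[kl[ii]] + 1L
  }
  counts
}

# direct O(n^2) cluster-potential sum, bypassing enumerate_pairs
oracle_cluster_energy <- function(atoms, boundary = NULL) {
  p <- bond_params()
  graph <- nucleotide_bond_graph()
  gk <- paste(pmin(graph$a, graph$b), pmax(graph$a, graph$b))
  all_a <- rbind(atoms, boundary)
  pos <- as.matrix(all_a[, c("x", "y", "z")])
  u <- 0
  n_core <- nrow(atoms)
  for (i in seq_len(nrow(all_a) - 1)) for (j in seq(i + 1, nrow(all_a))) {
    if (i > n_core && j > n_core) next  # boundary-boundary: not counted
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    k <- paste(min(all_a$name[i], all_a$name[j]),
               max(all_a$name[i], all_a$name[j]))
    hit <- match(k, gk)
    if (!is.na(hit)) {
      row <- p[p$pair_type == graph$pair_type[hit], ]
      u <- u + row$D_e * (exp(-2 * row$alpha * (r - row$r_e)) -
                            2 * exp(-row$alpha * (r - row$r_e)))
    } else if (i <= n_core && j <= n_core) {
      e <- sort(c(all_a$element[i], all_a$element[j]))
      row <- p[p$pair_type == paste(e[1], e[2], sep = "-"), ]
      s <- row$r_e / 2^(1 / 6)
      u <- u + 4 * row$D_e * ((s / r)^12 - (s / r)^6)
    }
  }
  u
}

# random break set generator for the classification property tests
random_break_set <- function(n_max = 15, n_bp = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- sample.int(n_max, 1)
  data.frame(strand = sample(0:1, n, replace = TRUE),
             nucleotide_index = sample.int(n_bp, n, replace = TRUE) - 1L)
}
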