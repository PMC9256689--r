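make_score_table <- function(scores) {
  structure(list(scores = data.table::as.data.table(scores),
                 assigned_energy = sum(scores$energy),
                 unassigned_energy = 0,
                 total_energy = sum(scores$energy)),
            class = "score_table")
}

test_that("breaks require strictly exceeding the bead threshold", {
  beads <- fixture_cg(4, "linear")
  ph <- beads[beads$moiety == "phosphate", ][1, ]
  thr <- ph$threshold_eV
  at <- make_score_table(data.frame(event_id = 1L, bead_id = ph$bead_id,
                                    energy = thr))
  expect_equal(nrow(find_breaks(at, beads)), 0)  # equality: no break
  above <- make_score_table(data.frame(event_id = 1L,
                                       bead_id = ph$bead_id,
                                       energy = thr + 1e-9))
  br <- find_breaks(above, beads)
  expect_equal(nrow(br), 1)
  expect_equal(br$trigger, "phosphate")
  expect_equal(br$strand, ph$strand)
  expect_equal(br$nucleotide_index, ph$nucleotide_index)
})

test_that("base beads never break and both moieties report 'both'", {
  beads <- fixture_cg(4, "linear")
  base <- beads[beads$moiety == "base", ][1, ]
  st <- make_score_table(data.frame(event_id = 1L,
                                    bead_id = base$bead_id,
                                    energy = 1e6))
  expect_equal(nrow(find_breaks(st, beads)), 0)
  nuc <- beads[beads$strand == 0 & beads$nucleotide_index == 2, ]
  both <- make_score_table(data.frame(
    event_id = 1L,
    bead_id = nuc$bead_id[nuc$moiety != "base"],
    energy = 100))
  br <- find_breaks(both, beads)
  expect_equal(nrow(br), 1)
  expect_equal(br$trigger, "both")
})

test_that("canonical break patterns classify to their textbook classes", {
  cl <- function(st, ni, topo = "linear", n_bp = NULL)
    classify_breaks(data.frame(strand = st, nucleotide_index = ni),
                    topology = topo, n_bp = n_bp)
  expect_equal(sum(cl(0, 50)), 1)
  expect_equal(cl(0, 50)[["SSB"]], 1)
  expect_equal(cl(c(0, 0), c(50, 55))[["SSBp"]], 1)
  expect_equal(cl(c(0, 1), c(50, 55))[["DSB"]], 1)
  expect_equal(cl(c(0, 1), c(50, 80))[["2SSB"]], 1)
  expect_equal(cl(c(0, 1, 0), c(50, 55, 58))[["DSBp"]], 1)
  expect_equal(cl(c(0, 1, 0, 1), c(50, 52, 58, 60))[["DSBpp"]], 1)
  # two isolated same-strand breaks: two SSBs, never a 2SSB
  v <- cl(c(0, 0), c(10, 100))
  expect_equal(v[["SSB"]], 2)
  expect_equal(v[["2SSB"]], 0)
})

test_that("circular classification wraps around the origin", {
  v <- classify_breaks(data.frame(strand = c(0, 1),
                                  nucleotide_index = c(1, 198)),
                       topology = "circular", n_bp = 200)
  expect_equal(v[["DSB"]], 1)
  lin <- classify_breaks(data.frame(strand = c(0, 1),
                                    nucleotide_index = c(1, 198)),
                         topology = "linear")
  expect_equal(lin[["2SSB"]], 1)
  expect_error(classify_breaks(data.frame(strand = 0,
                                          nucleotide_index = 1),
                               topology = "circular"), "n_bp")
})

test_that("classification matches the exhaustive oracle on random sets", {
  set.seed(101)
  for (k in 1:200) {
    topo <- if (k %% 2) "linear" else "circular"
    b <- random_break_set(12, 120)
    expect_equal(classify_breaks(b, topology = topo, n_bp = 120),
                 oracle_classify(b, topology = topo, n_bp = 120))
  }
})

test_that("damage tally aggregates per event and segment", {
  br <- data.frame(event_id = c(1L, 1L, 2L, 2L),
                   segment_id = c(0L, 0L, 0L, 1L),
                   strand = c(0L, 1L, 0L, 0L),
                   nucleotide_index = c(10L, 12L, 50L, 60L),
                   trigger = "phosphate")
  tl <- tally_damage(br, "linear", 100, dose = 2, total_bp = 1e6)
  expect_equal(tl$counts[["DSB"]], 1)  # event 1 pair
  expect_equal(tl$counts[["SSB"]], 2)  # events 2 x two segments
  expect_equal(nrow(tl$per_event), 3)
  empty <- tally_damage(br[0, ], "linear", 100)
  expect_equal(sum(empty$counts), 0)
})

test_that("yields divide counts by dose and Gbp with multiplicities", {
  br <- data.frame(event_id = 1L, segment_id = 0L, strand = c(0L, 1L),
                   nucleotide_index = c(10L, 60L), trigger = "phosphate")
  tl <- tally_damage(br, "linear", 100, dose = 4, total_bp = 5e8)
  y <- yields(tl)
  # one 2SSB lesion = 2 SSBs by default
  expect_equal(y$ssb_yield, 2 / (4 * 0.5))
  expect_equal(y$dsb_yield, 0)
  expect_true(is.na(y$ratio))
  y1 <- yields(tl, two_ssb_counts = 1)
  expect_equal(y1$ssb_yield, 1 / (4 * 0.5))
  tl_bad <- tally_damage(br, "linear", 100)
  expect_error(yields(tl_bad), "dose")
})

test_that("mean percentage error matches its definition", {
  expect_equal(mean_percentage_error(c(2, 1), c(1, 2)), 75)
  expect_equal(mean_percentage_error(5, 5), 0)
  expect_error(mean_percentage_error(1, c(1, 2)), "equal length")
  expect_error(mean_percentage_error(1, 0), "non-zero")
})
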