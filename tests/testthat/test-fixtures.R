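test_that("linear B-DNA has the expected atom inventory", {
  m <- fixture_model(10, "linear")
  # 21 heavy atoms per nucleotide, minus the two 5'-terminal phosphates
  expect_equal(nrow(m$atoms), 2 * 10 * 21 - 2 * 3)
  expect_equal(m$n_bp, 10L)
  expect_setequal(unique(m$atoms$strand), 0:1)
  expect_setequal(unique(m$atoms$moiety),
                  c("phosphate", "deoxyribose", "base"))
  # 5'-first nucleotide of each strand lacks P, OP1, OP2
  first <- m$atoms[m$atoms$nucleotide_index == 0, ]
  expect_false(any(first$name %in% c("P", "OP1", "OP2")))
})

test_that("helical rise and twist are respected on the linear form", {
  m <- fixture_model(12, "linear")
  a <- m$atoms[m$atoms$strand == 0 & m$atoms$name == "C1'", ]
  a <- a[order(a$nucleotide_index), ]
  expect_equal(diff(a$z), rep(3.38, 11), tolerance = 1e-9)
  # radial distance from the axis is constant; azimuth advances 36 deg
  r <- sqrt(a$x^2 + a$y^2)
  expect_equal(r, rep(r[1], 12), tolerance = 1e-9)
  th <- atan2(a$y, a$x)
  dth <- diff(th) %% (2 * pi)
  expect_equal(dth, rep(36 * pi / 180, 11), tolerance = 1e-9)
})

test_that("intra-nucleotide bond lengths sit at the parameter-table equilibria", {
  m <- fixture_model(6, "linear")
  a <- m$atoms[m$atoms$strand == 1 & m$atoms$nucleotide_index == 3, ]
  pos <- function(nm) unlist(a[a$name == nm, c("x", "y", "z")])
  d <- function(p, q) sqrt(sum((pos(p) - pos(q))^2))
  expect_equal(d("C1'", "C2'"), 1.54, tolerance = 0.1)
  expect_equal(d("C2'", "C3'"), 1.54, tolerance = 0.1)
  expect_equal(d("C3'", "C4'"), 1.54, tolerance = 0.1)
  expect_equal(d("C4'", "C5'"), 1.54, tolerance = 0.1)
  expect_equal(d("C1'", "O4'"), 1.43, tolerance = 0.1)
  expect_equal(d("C4'", "O4'"), 1.43, tolerance = 0.1)
  expect_equal(d("C3'", "O3'"), 1.43, tolerance = 0.1)
  expect_equal(d("C5'", "O5'"), 1.43, tolerance = 0.1)
  # the phosphate cluster carries its calibrated geometry exactly
  expect_equal(d("P", "OP1"), 1.480, tolerance = 1e-9)
  expect_equal(d("P", "OP2"), 1.482, tolerance = 1e-9)
  expect_equal(d("P", "O5'"), 1.598, tolerance = 1e-9)
})

test_that("strands are antiparallel", {
  m <- fixture_model(10, "linear")
  c1 <- m$atoms[m$atoms$name == "C1'", ]
  z0 <- c1$z[c1$strand == 0][order(c1$nucleotide_index[c1$strand == 0])]
  z1 <- c1$z[c1$strand == 1][order(c1$nucleotide_index[c1$strand == 1])]
  # strand 0 index runs with +z, strand 1 against it
  expect_true(all(diff(z0) > 0))
  expect_true(all(diff(z1) < 0))
})

test_that("circular forms close and keep every phosphate", {
  m <- fixture_model(40, "circular", "relaxed")
  expect_equal(nrow(m$atoms), 2 * 40 * 21)
  # axis is a circle of circumference n_bp * rise
  c1 <- m$atoms[m$atoms$strand == 0 & m$atoms$name == "C1'", ]
  expect_lt(max(abs(c1$z)), 7)  # near the axis plane
  # first and last nucleotide are spatial neighbours (closure)
  p0 <- unlist(c1[c1$nucleotide_index == 0, c("x", "y", "z")])
  pn <- unlist(c1[c1$nucleotide_index == 39, c("x", "y", "z")])
  expect_lt(sqrt(sum((p0 - pn)^2)), 2.5 * 3.38)
})

test_that("supercoiled form is a closed curve of the same contour length", {
  m <- fixture_model(60, "circular", "supercoiled")
  expect_equal(m$form, "supercoiled")
  c1 <- m$atoms[m$atoms$strand == 0 & m$atoms$name == "C1'", ]
  c1 <- c1[order(c1$nucleotide_index), ]
  steps <- sqrt(rowSums(diff(as.matrix(c1[, c("x", "y", "z")]))^2))
  # per-bp spacing stays near the rise (the axis is arclength-uniform)
  expect_true(all(steps > 0.5 & steps < 10))
  # the figure-eight folds the curve: max extent well below a circle's
  circ <- fixture_model(60, "circular", "relaxed")
  ext <- function(mm) max(dist(mm$atoms[mm$atoms$name == "P" &
                                          mm$atoms$strand == 0,
                                        c("x", "y", "z")]))
  expect_lt(ext(m), ext(circ))
})

test_that("invalid fixture requests are rejected", {
  expect_error(build_bdna(1), "at least 2")
  expect_error(build_bdna(10, "linear", "supercoiled"), "only form")
  expect_error(build_bdna(10, "circular", "relaxed"), "n_bp >= 30")
  expect_error(build_bdna(40, "circular", "straight"), "relaxed")
})

test_that("PDB files round-trip the model", {
  m <- fixture_model(5, "linear")
  f <- tempfile(fileext = ".pdb")
  write_pdb(m, f)
  m2 <- read_pdb(f)
  expect_equal(m2$n_bp, m$n_bp)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  # PDB stores 3 decimals
  a <- m$atoms[order(m$atoms$strand, m$atoms$nucleotide_index,
                     m$atoms$name), ]
  b <- m2$atoms[order(m2$atoms$strand, m2$atoms$nucleotide_index,
                      m2$atoms$name), ]
  expect_equal(a$name, b$name)
  expect_equal(a$moiety, b$moiety)
  expect_equal(a$x, b$x, tolerance = 1e-3)
  expect_equal(a$y, b$y, tolerance = 1e-3)
  expect_equal(a$z, b$z, tolerance = 1e-3)
  unlink(f)
})

test_that("read_pdb rejects non-nucleic and missing files", {
  expect_error(read_pdb(tempfile()), "not found")
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  expect_error(read_pdb(f), "non-nucleic")
  unlink(f)
})

test_that("read_pdb warns about incomplete nucleotides", {
  m <- fixture_model(3, "linear")
  m$atoms <- m$atoms[!(m$atoms$name == "O3'" &
                         m$atoms$nucleotide_index == 1 &
                         m$atoms$strand == 0), ]
  f <- tempfile(fileext = ".pdb")
  write_pdb(m, f)
  expect_warning(read_pdb(f), "missing backbone atom")
  unlink(f)
})
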