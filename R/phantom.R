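# Spherical water phantom filled with randomly placed, randomly oriented
# DNA segment copies. Each segment lives in a cuboid "mother volume"
# (its bead bounding box plus a 1 nm margin); placements are rejected
# until no two mother volumes intersect and all lie inside the sphere.

#' Random rotation matrix (uniform over SO(3))
#' @param n how many matrices.
#' @return list of 3x3 orthonormal matrices with determinant +1.
#' @keywords internal
.random_rotations <- function(n) {
  lapply(seq_len(n), function(i) {
    q <- qr(matrix(stats::rnorm(9), 3, 3))
    Q <- qr.Q(q)
    d <- sign(diag(qr.R(q))); d[d == 0] <- 1
    Q <- Q %*% diag(d)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  })
}

# separating-axis test for two oriented boxes
# each box: list(center (nm), half (3), rot (3x3, columns = local axes))
.obb_intersect <- function(b1, b2) {
  A <- b1$rot; B <- b2$rot
  a <- b1$half; b <- b2$half
  Tv <- as.numeric(t(A) %*% (b2$center - b1$center))
  R <- t(A) %*% B
  absR <- abs(R) + 1e-12
  for (i in 1:3)  # A's axes
    if (abs(Tv[i]) > a[i] + sum(absR[i, ] * b)) return(FALSE)
  for (j in 1:3)  # B's axes
    if (abs(sum(R[, j] * Tv)) > sum(absR[, j] * a) + b[j]) return(FALSE)
  for (i in 1:3) for (j in 1:3) {  # cross products
    i1 <- (i %% 3) + 1; i2 <- (i1 %% 3) + 1
    j1 <- (j %% 3) + 1; j2 <- (j1 %% 3) + 1
    lhs <- abs(Tv[i2] * R[i1, j] - Tv[i1] * R[i2, j])
    rhs <- a[i1] * absR[i2, j] + a[i2] * absR[i1, j] +
      b[j1] * absR[i, j2] + b[j2] * absR[i, j1]
    if (lhs > rhs) return(FALSE)
  }
  TRUE
}

#' Place DNA segment copies inside a spherical phantom
#'
#' Positions are uniform in the sphere, orientations uniform over
#' rotations; a placement is rejected and redrawn whenever its mother
#' volume (bead bounding box + margin) pokes out of the sphere or
#' intersects an already-placed mother volume (separating-axis test,
#' restricted to neighbouring grid cells for speed). Form counts are
#' exact: `round(fraction * n_segments)` supercoiled, the rest relaxed.
#'
#' @param n_segments number of segment copies to place.
#' @param radius_nm phantom sphere radius in nm (3 um = 3000 nm in the
#'   full-scale configuration).
#' @param cg_models named list of bead tables (from [build_cg_model()]),
#'   one per form used, e.g. `list(supercoiled = ..., relaxed = ...)`.
#'   A single unnamed model is used for all forms.
#' @param form_fractions named numeric, e.g.
#'   `c(supercoiled = 0.9, relaxed = 0.1)`; must sum to 1.
#' @param seed RNG seed.
#' @param margin_nm mother-volume margin around the bead bounding box.
#' @param max_attempts attempts per segment before giving up.
#' @return object of class `phantom`: list with `radius_nm`,
#'   `placements` (data.frame: `segment_id`, `form`, `tx`, `ty`, `tz` nm,
#'   `r11`..`r33`), `boxes` (list of oriented boxes), `cg_models`,
#'   `bp_per_segment`, `total_bp`.
#' @export
place_segments <- function(n_segments, radius_nm, cg_models,
                           form_fractions = c(supercoiled = 0.9,
                                              relaxed = 0.1),
                           seed = 1L, margin_nm = 1,
                           max_attempts = 1000L) {
  if (n_segments < 1) stop("n_segments must be >= 1")
  if (abs(sum(form_fractions) - 1) > 1e-9)
    stop("form_fractions must sum to 1")
  if (is.data.frame(cg_models)) cg_models <- list(cg_models)
  if (is.null(names(cg_models)) || all(names(cg_models) == "")) {
    cg_models <- stats::setNames(rep(cg_models[1], length(form_fractions)),
                                 names(form_fractions))
  }
  missing_forms <- setdiff(names(form_fractions)[form_fractions > 0],
                           names(cg_models))
  if (length(missing_forms))
    stop("no cg model supplied for form(s): ",
         paste(missing_forms, collapse = ", "))

  # exact form counts
  counts <- round(form_fractions * n_segments)
  counts[length(counts)] <- n_segments - sum(counts[-length(counts)])
  forms <- rep(names(counts), counts)

  # per-form half-extents (nm): beads are in Angstrom
  half_of <- lapply(cg_models, function(b) {
    xyz <- as.matrix(b[, c("x", "y", "z")]) / 10
    rad <- max(b$scoring_radius) / 10
    (apply(xyz, 2, max) - apply(xyz, 2, min)) / 2 + rad + margin_nm
  })
  ctr_of <- lapply(cg_models, function(b) {
    xyz <- as.matrix(b[, c("x", "y", "z")]) / 10
    (apply(xyz, 2, max) + apply(xyz, 2, min)) / 2
  })
  max_half <- max(unlist(half_of))
  diam <- 2 * sqrt(3) * max_half
  vol_frac <- sum(sapply(forms, function(f) prod(2 * half_of[[f]]))) /
    (4 / 3 * pi * radius_nm^3)
  if (vol_frac > 0.35)
    stop(sprintf("phantom too small: requested packing fraction %.2f",
                 vol_frac))

  set.seed(seed)
  boxes <- vector("list", n_segments)
  cell_of <- function(p) paste(floor(p / diam), collapse = ",")
  grid <- new.env(parent = emptyenv())
  neighbours <- function(p) {
    base <- floor(p / diam)
    idx <- expand.grid(-1:1, -1:1, -1:1)
    apply(idx, 1, function(o) paste(base + o, collapse = ","))
  }
  placements <- data.frame(segment_id = seq_len(n_segments) - 1L,
                           form = forms,
                           tx = 0, ty = 0, tz = 0,
                           r11 = 0, r12 = 0, r13 = 0,
                           r21 = 0, r22 = 0, r23 = 0,
                           r31 = 0, r32 = 0, r33 = 0,
                           stringsAsFactors = FALSE)
  for (i in seq_len(n_segments)) {
    half <- half_of[[forms[i]]]
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      # uniform point in the sphere
      repeat {
        p <- stats::runif(3, -radius_nm, radius_nm)
        if (sum(p^2) <= radius_nm^2) break
      }
      Rm <- .random_rotations(1)[[1]]
      # the box is centred on the segment's local bounding-box centre,
      # which need not be the local origin
      bc <- p + as.numeric(Rm %*% ctr_of[[forms[i]]])
      box <- list(center = bc, half = half, rot = Rm)
      # inside sphere: all 8 corners
      corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) *
        rep(half, each = 8)
      world <- t(Rm %*% t(corners)) + matrix(bc, 8, 3, byrow = TRUE)
      if (any(rowSums(world^2) > radius_nm^2)) next
      # overlap with neighbours
      clash <- FALSE
      for (cell in neighbours(bc)) {
        for (j in grid[[cell]] %||% integer(0)) {
          if (.obb_intersect(box, boxes[[j]])) { clash <- TRUE; break }
        }
        if (clash) break
      }
      if (clash) next
      boxes[[i]] <- box
      cl <- cell_of(bc)
      grid[[cl]] <- c(grid[[cl]], i)
      placements[i, c("tx", "ty", "tz")] <- p
      placements[i, 6:14] <- as.numeric(t(Rm))
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf(paste0("could not place segment %d after %d attempts ",
                          "(packing fraction %.3f)"),
                   i, max_attempts, vol_frac))
  }
  bp_per_segment <- vapply(cg_models, function(b)
    attr(b, "n_bp") %||% length(unique(b$nucleotide_index)), numeric(1))
  total_bp <- sum(bp_per_segment[forms])
  structure(list(radius_nm = radius_nm, placements = placements,
                 boxes = boxes, cg_models = cg_models,
                 ctr_of = ctr_of,
                 bp_per_segment = bp_per_segment, total_bp = total_bp),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "Phantom: r = %g nm, %d segments, %g bp total, %.3g bp/nm^3\n",
    x$radius_nm, nrow(x$placements), x$total_bp, bp_density(x)))
  invisible(x)
}

#' Base-pair density of a phantom
#'
#' @param phantom a `phantom`.
#' @return total base pairs divided by the sphere volume, bp/nm^3.
#' @export
bp_density <- function(phantom) {
  if (nrow(phantom$placements) == 0) stop("phantom has no placements")
  phantom$total_bp / (4 / 3 * pi * phantom$radius_nm^3)
}

#' World-frame bead table of a phantom
#'
#' Applies every placement's rotation and translation to its segment's
#' bead model and concatenates the result.
#'
#' @param phantom a `phantom`.
#' @return data.frame of beads with coordinates in nm, globally unique
#'   `bead_id`, and the placement's `segment_id`.
#' @export
phantom_beads <- function(phantom) {
  pl <- phantom$placements
  out <- vector("list", nrow(pl))
  for (i in seq_len(nrow(pl))) {
    b <- phantom$cg_models[[pl$form[i]]]
    Rm <- matrix(as.numeric(pl[i, 6:14]), 3, 3, byrow = TRUE)
    xyz <- as.matrix(b[, c("x", "y", "z")]) / 10  # A -> nm
    world <- t(Rm %*% t(xyz)) +
      matrix(as.numeric(pl[i, c("tx", "ty", "tz")]),
             nrow(xyz), 3, byrow = TRUE)
    o <- b
    o$segment_id <- pl$segment_id[i]
    o$x <- world[, 1]; o$y <- world[, 2]; o$z <- world[, 3]
    o$scoring_radius_nm <- b$scoring_radius / 10
    out[[i]] <- o
  }
  beads <- do.call(rbind, out)
  beads$bead_id <- seq_len(nrow(beads)) - 1L
  attr(beads, "n_bp") <- phantom$bp_per_segment
  attr(beads, "radius_nm") <- phantom$radius_nm
  beads
}

#' Write a phantom layout as TSV
#'
#' Columns: segment_id, form, tx, ty, tz (nm), r11..r33 (row-major
#' rotation).
#'
#' @param phantom a `phantom`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  utils::write.table(phantom$placements, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
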