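# Coarse-graining: partition nucleotide atoms into phosphate /
# deoxyribose / base clusters, estimate van der Waals union volumes,
# derive bead radii and attach strand-break thresholds.

#' Van der Waals radii (Bondi) for the elements of DNA heavy atoms
#'
#' @return named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() c(C = 1.70, N = 1.55, O = 1.52, P = 1.80)

#' Partition the atoms of one nucleotide into moiety clusters
#'
#' Assignment is by atom name: P, OP1, OP2 and O5' form the phosphate
#' cluster; C1'-C5', O4' and O3' form the deoxyribose cluster; recognised
#' base-ring atoms form the base. O5' and O3' are deliberately split
#' between phosphate and sugar so the two boundary ester bonds are
#' counted once each.
#'
#' @param atoms data.frame of atoms sharing one `nucleotide_index` and
#'   `strand` (columns as in a `dna_model`).
#' @return list of class `moiety_partition` with data.frames `phosphate`,
#'   `deoxyribose`, `base` plus `nucleotide_index` and `strand`. A
#'   5'-terminal nucleotide yields an empty (0-row) phosphate cluster.
#' @export
partition_nucleotide <- function(atoms) {
  if (length(unique(atoms$nucleotide_index)) > 1 ||
      length(unique(atoms$strand)) > 1)
    stop("atoms must belong to a single nucleotide (one index, one strand)")
  known <- c(.phosphate_names, .sugar_names, .base_names)
  bad <- setdiff(atoms$name, known)
  if (length(bad))
    stop("unrecognized atom name(s): ", paste(bad, collapse = ", "))
  structure(list(
    phosphate = atoms[atoms$name %in% .phosphate_names, , drop = FALSE],
    deoxyribose = atoms[atoms$name %in% .sugar_names, , drop = FALSE],
    base = atoms[atoms$name %in% .base_names, , drop = FALSE],
    nucleotide_index = atoms$nucleotide_index[1],
    strand = atoms$strand[1]
  ), class = "moiety_partition")
}

#' Volume of a union of atomic van der Waals spheres
#'
#' Estimates the volume of the union of spheres centred on the atoms,
#' either by Monte-Carlo rejection sampling in the bounding box
#' (`method = "monte_carlo"`) or by voxel counting on a regular grid
#' (`method = "grid"`).
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`
#'   (Angstrom), or a numeric matrix of centres (then supply `radii`).
#' @param radii sphere radii in Angstrom; defaults to [vdw_radii()] looked
#'   up by element.
#' @param method `"monte_carlo"` or `"grid"`.
#' @param samples number of Monte-Carlo sample points.
#' @param spacing grid spacing in Angstrom.
#' @param seed RNG seed for the Monte-Carlo method.
#' @return volume in nm^3.
#' @export
#' @examples
#' # single sphere of radius 2 A: 4/3 pi 8 = 33.51 A^3 = 0.03351 nm^3
#' union_volume(matrix(0, 1, 3), radii = 2, samples = 2e5)
union_volume <- function(atoms, radii = NULL,
                         method = c("monte_carlo", "grid"),
                         samples = 1e6, spacing = 0.05, seed = 1L) {
  method <- match.arg(method)
  if (is.data.frame(atoms)) {
    centers <- as.matrix(atoms[, c("x", "y", "z")])
    if (is.null(radii)) radii <- unname(vdw_radii()[atoms$element])
  } else {
    centers <- as.matrix(atoms)
    if (is.null(radii)) stop("supply radii when atoms is a bare matrix")
  }
  if (nrow(centers) == 0) stop("cannot compute the volume of zero atoms")
  if (anyNA(radii) || any(radii <= 0)) stop("radii must be positive")
  radii <- rep_len(radii, nrow(centers))

  lo <- apply(centers - radii, 2, min)
  hi <- apply(centers + radii, 2, max)
  inside_any <- function(pts) {
    inside <- rep(FALSE, nrow(pts))
    for (k in seq_len(nrow(centers)))
      inside <- inside |
        (rowSums(sweep(pts, 2, centers[k, ])^2) <= radii[k]^2)
    inside
  }
  if (method == "monte_carlo") {
    set.seed(seed)
    pts <- cbind(stats::runif(samples, lo[1], hi[1]),
                 stats::runif(samples, lo[2], hi[2]),
                 stats::runif(samples, lo[3], hi[3]))
    vol_A3 <- mean(inside_any(pts)) * prod(hi - lo)
  } else {
    gx <- seq(lo[1] + spacing / 2, hi[1], by = spacing)
    gy <- seq(lo[2] + spacing / 2, hi[2], by = spacing)
    gz <- seq(lo[3] + spacing / 2, hi[3], by = spacing)
    count <- 0
    # sweep one z-slab at a time to bound memory
    for (z in gz) {
      pts <- cbind(rep(gx, times = length(gy)),
                   rep(gy, each = length(gx)), z)
      count <- count + sum(inside_any(pts))
    }
    vol_A3 <- count * spacing^3
  }
  vol_A3 / 1000  # A^3 -> nm^3
}

#' Equivalent-sphere radius from a union volume
#'
#' `r = (3 V / (4 pi))^(1/3)`, converted from nm^3 to Angstrom.
#'
#' @param V volume in nm^3.
#' @return radius in Angstrom.
#' @export
#' @examples
#' radius_from_volume(c(0.050, 0.084, 0.104))  # ~2.3, 2.7, 2.9
radius_from_volume <- function(V) {
  if (any(V <= 0)) stop("volume must be positive")
  (3 * (V * 1000) / (4 * pi))^(1 / 3)
}

HYDRATION_RADIUS <- 3.4  # Angstrom, first hydration shell around DNA

#' Build a coarse-grained bead model from an atomic DNA model
#'
#' Each complete nucleotide becomes three beads (phosphate, deoxyribose,
#' base) centred on the unweighted centroid of its heavy-atom cluster.
#' Bead construction radii come from the van der Waals union volume of
#' the cluster; scoring radii are either those radii (`scoring =
#' "vdwr"`) or the 3.4 Angstrom hydration-shell radius for the two
#' backbone moieties (`scoring = "hydration"`, the default). Strand-break
#' threshold energies (eV) are the cluster pair-potential magnitudes for
#' phosphate and deoxyribose beads; base beads carry no threshold (they
#' are not break sites but still occupy volume in deposit assignment).
#' A 5'-terminal residue (no P atom) contributes no phosphate bead: its
#' O5' is a terminal hydroxyl, not a break site.
#'
#' Since every nucleotide shares the same rigid cluster geometry, volumes
#' and thresholds are computed once per distinct (moiety, atom-set)
#' signature and cached across nucleotides.
#'
#' @param model a `dna_model`.
#' @param scoring `"hydration"` or `"vdwr"`.
#' @param volumes optional named vector (nm^3) with entries `phosphate`,
#'   `deoxyribose`, `base` to bypass union-volume estimation (e.g. the
#'   published 0.050/0.084/0.104 values).
#' @param params bond parameter table, see [bond_params()].
#' @param samples Monte-Carlo samples per union-volume estimate.
#' @return data.frame of beads with columns `bead_id`, `segment_id`,
#'   `strand`, `nucleotide_index`, `moiety`, `x`, `y`, `z` (Angstrom),
#'   `radius_vdwr`, `scoring_radius` (Angstrom), `threshold_eV` (NA for
#'   base beads).
#' @export
build_cg_model <- function(model, scoring = c("hydration", "vdwr"),
                           volumes = NULL, params = bond_params(),
                           samples = 2e5) {
  scoring <- match.arg(scoring)
  a <- model$atoms
  key <- paste(a$strand, a$nucleotide_index)
  ukey <- unique(key)
  vol_cache <- new.env(parent = emptyenv())
  thr_cache <- new.env(parent = emptyenv())

  out <- vector("list", 3L * length(ukey))
  n_out <- 0L
  for (k in ukey) {
    nuc <- a[key == k, , drop = FALSE]
    part <- partition_nucleotide(nuc)
    for (m in c("phosphate", "deoxyribose", "base")) {
      cl <- part[[m]]
      if (nrow(cl) == 0) next  # 5'-terminus without phosphate
      # a 5'-terminal residue keeps its O5' (as a hydroxyl) but has no
      # phosphate group: no bead, and no break site
      if (m == "phosphate" && !"P" %in% cl$name) next
      sig <- paste(m, paste(sort(cl$name), collapse = ","))
      if (!is.null(volumes) && m %in% names(volumes)) {
        vol <- volumes[[m]]
      } else if (!is.null(vol_cache[[sig]])) {
        vol <- vol_cache[[sig]]
      } else {
        vol <- union_volume(cl, samples = samples)
        vol_cache[[sig]] <- vol
      }
      r <- radius_from_volume(vol)
      thr <- NA_real_
      if (m != "base") {
        if (!is.null(thr_cache[[sig]])) {
          thr <- thr_cache[[sig]]
        } else {
          boundary <- if (m == "deoxyribose" && "O5'" %in% nuc$name)
            nuc[nuc$name == "O5'", , drop = FALSE] else NULL
          thr <- cluster_potential(cl, boundary_atoms = boundary,
                                   params = params)$threshold
          thr_cache[[sig]] <- thr
        }
      }
      sr <- if (scoring == "hydration" && m != "base")
        max(HYDRATION_RADIUS, 0) else r
      n_out <- n_out + 1L
      out[[n_out]] <- data.frame(
        segment_id = cl$segment_id[1], strand = part$strand,
        nucleotide_index = part$nucleotide_index, moiety = m,
        x = mean(cl$x), y = mean(cl$y), z = mean(cl$z),
        radius_vdwr = r, scoring_radius = sr, threshold_eV = thr,
        stringsAsFactors = FALSE
      )
    }
  }
  beads <- do.call(rbind, out[seq_len(n_out)])
  beads <- beads[order(beads$strand, beads$nucleotide_index,
                       match(beads$moiety,
                             c("phosphate", "deoxyribose", "base"))), ]
  beads <- cbind(bead_id = seq_len(nrow(beads)) - 1L, beads)
  rownames(beads) <- NULL
  attr(beads, "n_bp") <- model$n_bp
  attr(beads, "topology") <- model$topology
  beads
}

#' Write a CG bead table to the package's plain-text geometry format
#'
#' One line per bead: `segment_id strand nucleotide_index moiety x y z
#' radius_vdwr scoring_radius threshold_eV`, whitespace-separated, with
#' `#` comment lines and a versioned header. Coordinates round-trip to
#' six decimals.
#'
#' @param beads bead data.frame from [build_cg_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cg <- function(beads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# cgdamage cg-geometry v1",
               sprintf("# n_bp %d topology %s",
                       attr(beads, "n_bp") %||% -1L,
                       attr(beads, "topology") %||% "unknown"),
               "# segment strand nucleotide moiety x y z r_vdwr r_scoring threshold_eV"),
             con)
  writeLines(sprintf("%d %d %d %s %.6f %.6f %.6f %.6f %.6f %s",
                     beads$segment_id, beads$strand,
                     beads$nucleotide_index, beads$moiety,
                     beads$x, beads$y, beads$z,
                     beads$radius_vdwr, beads$scoring_radius,
                     ifelse(is.na(beads$threshold_eV), "NA",
                            sprintf("%.6f", beads$threshold_eV))),
             con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a CG bead table written by [write_cg()]
#'
#' @param path file path.
#' @return bead data.frame as produced by [build_cg_model()].
#' @export
read_cg <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (!length(hdr) || !grepl("cgdamage cg-geometry v1", hdr[1]))
    stop("not a cgdamage cg-geometry v1 file: ", path)
  meta <- regmatches(hdr, regexec("n_bp (\\d+) topology (\\w+)", hdr))
  meta <- Filter(length, meta)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(body, "\\s+")
  bad <- which(lengths(f) != 10)
  if (length(bad))
    stop("malformed cg line(s): ", paste(utils::head(bad, 3), collapse = ", "))
  m <- do.call(rbind, f)
  beads <- data.frame(
    bead_id = seq_along(body) - 1L,
    segment_id = as.integer(m[, 1]), strand = as.integer(m[, 2]),
    nucleotide_index = as.integer(m[, 3]), moiety = m[, 4],
    x = as.numeric(m[, 5]), y = as.numeric(m[, 6]), z = as.numeric(m[, 7]),
    radius_vdwr = as.numeric(m[, 8]), scoring_radius = as.numeric(m[, 9]),
    threshold_eV = suppressWarnings(as.numeric(m[, 10])),
    stringsAsFactors = FALSE
  )
  if (length(meta)) {
    attr(beads, "n_bp") <- as.integer(meta[[1]][2])
    attr(beads, "topology") <- meta[[1]][3]
  }
  beads
}
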