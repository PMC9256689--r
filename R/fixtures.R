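# Idealised DNA atomic models: linear B-DNA, closed-circular plasmids and
# a figure-eight supercoiled form, plus PDB round-trip via bio3d.

B_DNA_RISE <- 3.38   # Angstrom per base pair
B_DNA_TWIST <- 36    # degrees per base pair

#' Build an idealised B-DNA atomic model
#'
#' Generates a two-strand heavy-atom model from the shipped nucleotide
#' template on a canonical B-DNA helix (rise 3.38 Angstrom, twist 36
#' degrees per bp). The helical axis is a straight line (`form =
#' "straight"`), a closed circle (`topology = "circular"`, `form =
#' "relaxed"`) or a closed figure-eight with one axis crossing (`form =
#' "supercoiled"`), emulating the dominant shape of dried supercoiled
#' plasmids seen in TEM. Strand 1 is antiparallel: its nucleotide index
#' runs opposite to the spatial direction of strand 0.
#'
#' @param n_bp number of base pairs (>= 2; circular topologies need
#'   >= 30).
#' @param topology `"linear"` or `"circular"`.
#' @param form `"straight"` (linear only), `"relaxed"` or `"supercoiled"`
#'   (circular only).
#' @param seed integer; kept for interface symmetry with the stochastic
#'   generators — construction is deterministic.
#' @param segment_id integer id stamped on every atom.
#' @return object of class `dna_model`: list with `atoms` (data.frame:
#'   `element`, `name`, `x`, `y`, `z`, `nucleotide_index`, `strand`,
#'   `segment_id`, `moiety`), `n_bp`, `topology`, `form`.
#' @export
#' @examples
#' m <- build_bdna(10)
#' nrow(m$atoms)  # 20 nucleotides x 21 heavy atoms
build_bdna <- function(n_bp, topology = c("linear", "circular"),
                       form = NULL, seed = 1L, segment_id = 0L) {
  topology <- match.arg(topology)
  if (is.null(form))
    form <- if (topology == "linear") "straight" else "relaxed"
  form <- match.arg(form, c("straight", "relaxed", "supercoiled"))
  if (n_bp < 2) stop("n_bp must be at least 2")
  if (topology == "linear" && form != "straight")
    stop("linear topology supports only form = 'straight'")
  if (topology == "circular") {
    if (form == "straight")
      stop("circular topology requires form 'relaxed' or 'supercoiled'")
    if (n_bp < 30)
      stop("circular topology needs n_bp >= 30 (got ", n_bp, ")")
  }

  axis <- .axis_frames(n_bp, topology, form)
  tpl <- nucleotide_template()
  tlocal <- as.matrix(tpl[, c("x", "y", "z")])
  # shift backbone out to helical radius (P at ~9 A from the axis)
  tlocal[, 1] <- tlocal[, 1] + 5.9
  # strand 1: rotate 180 degrees about the local x axis (antiparallel)
  tflip <- tlocal %*% diag(c(1, -1, -1))

  rows <- vector("list", 2L * n_bp)
  twist <- B_DNA_TWIST * pi / 180
  strand_offset <- 154 * pi / 180  # backbone-backbone angular offset
  for (i in seq_len(n_bp) - 1L) {
    for (s in 0:1) {
      step <- if (s == 0) i else n_bp - 1L - i  # axis step of this index
      th <- step * twist + if (s == 0) 0 else strand_offset
      loc <- if (s == 0) tlocal else tflip
      # in-plane rotation by the helical twist, then map into the axis
      # frame (N, B span the plane, T is the tangent)
      xy <- cbind(cos(th) * loc[, 1] - sin(th) * loc[, 2],
                  sin(th) * loc[, 1] + cos(th) * loc[, 2])
      fr <- axis[[step + 1L]]
      world <- matrix(fr$p, nrow(loc), 3, byrow = TRUE) +
        xy[, 1] %o% fr$n + xy[, 2] %o% fr$b + loc[, 3] %o% fr$t
      rows[[2L * i + s + 1L]] <- data.frame(
        element = tpl$element, name = tpl$name,
        x = world[, 1], y = world[, 2], z = world[, 3],
        nucleotide_index = i, strand = s, segment_id = segment_id,
        moiety = tpl$moiety, stringsAsFactors = FALSE
      )
    }
  }
  atoms <- do.call(rbind, rows)
  # linear models: drop the 5' phosphate of each strand's first nucleotide
  if (topology == "linear") {
    drop <- atoms$nucleotide_index == 0L &
      atoms$name %in% c("P", "OP1", "OP2")
    atoms <- atoms[!drop, , drop = FALSE]
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, n_bp = as.integer(n_bp),
                 topology = topology, form = form),
            class = "dna_model")
}

#' @export
print.dna_model <- function(x, ...) {
  cat(sprintf("DNA model: %d bp, %s/%s, %d atoms\n",
              x$n_bp, x$topology, x$form, nrow(x$atoms)))
  invisible(x)
}

# Orthonormal frames (point p, tangent t, normal n, binormal b) along the
# helical axis, one per base-pair step.
.axis_frames <- function(n_bp, topology, form) {
  L <- n_bp * B_DNA_RISE
  if (topology == "linear") {
    return(lapply(seq_len(n_bp) - 1L, function(i)
      list(p = c(0, 0, i * B_DNA_RISE),
           t = c(0, 0, 1), n = c(1, 0, 0), b = c(0, 1, 0))))
  }
  if (form == "relaxed") {
    R <- L / (2 * pi)
    return(lapply(seq_len(n_bp) - 1L, function(i) {
      phi <- i * B_DNA_RISE / R
      list(p = R * c(cos(phi), sin(phi), 0),
           t = c(-sin(phi), cos(phi), 0),
           n = c(-cos(phi), -sin(phi), 0),   # toward the circle centre
           b = c(0, 0, 1))
    }))
  }
  # supercoiled: figure-eight (Gerono-type lemniscate) with the two lobes
  # offset in z so the single crossing does not self-intersect
  curve <- function(t, a) cbind(a * sin(t), a * sin(t) * cos(t),
                                0.18 * a * cos(t))
  tt <- seq(0, 2 * pi, length.out = 4001)
  arc1 <- function(a) {
    p <- curve(tt, a)
    sum(sqrt(rowSums(diff(p)^2)))
  }
  a <- stats::uniroot(function(a) arc1(a) - L,
                      c(L / 20, L), tol = 1e-9)$root
  p <- curve(tt, a)
  s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  # constant-speed reparametrisation at one rise per step
  targets <- (seq_len(n_bp) - 1L) * B_DNA_RISE
  ti <- stats::approx(s, tt, xout = targets, rule = 2)$y
  eps <- 1e-5
  lapply(seq_len(n_bp), function(k) {
    t0 <- ti[k]
    pt <- drop(curve(t0, a))
    tg <- drop(curve(t0 + eps, a) - curve(t0 - eps, a))
    tg <- tg / sqrt(sum(tg^2))
    ref <- c(0, 0, 1)
    if (abs(sum(ref * tg)) > 0.95) ref <- c(1, 0, 0)
    nn <- ref - sum(ref * tg) * tg
    nn <- nn / sqrt(sum(nn^2))
    bb <- c(tg[2] * nn[3] - tg[3] * nn[2],
            tg[3] * nn[1] - tg[1] * nn[3],
            tg[1] * nn[2] - tg[2] * nn[1])
    list(p = pt, t = tg, n = nn, b = bb)
  })
}

#' Write a DNA model to a PDB file
#'
#' One chain per strand (A = strand 0, B = strand 1); residues are written
#' as DA with residue numbers `nucleotide_index + 1`.
#'
#' @param model a `dna_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$nucleotide_index + 1L,
    resid = rep("DA", nrow(a)),
    chain = ifelse(a$strand == 0, "A", "B"),
    elety = a$name,
    elesy = a$element
  )
  invisible(path)
}

.nucleic_resids <- c("DA", "DT", "DG", "DC", "A", "T", "G", "C", "U", "DU")

#' Read a DNA model from a PDB file
#'
#' Accepts standard ATOM records with nucleic-acid residue names (DA, DT,
#' DG, DC and the one-letter RNA/DNA variants). Chains map to strands in
#' order of appearance; residue numbers map to `nucleotide_index`
#' (0-based). Files containing protein residues are rejected.
#'
#' @param path PDB file path.
#' @param topology,form annotations to stamp on the returned model (a PDB
#'   file does not carry them).
#' @param segment_id integer id stamped on every atom.
#' @return a `dna_model`.
#' @export
read_pdb <- function(path, topology = "linear", form = "straight",
                     segment_id = 0L) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in '", path, "'")
  bad <- setdiff(unique(at$resid), .nucleic_resids)
  if (length(bad))
    stop("unsupported (non-nucleic) residues in '", path, "': ",
         paste(bad, collapse = ", "))
  chains <- unique(at$chain)
  if (length(chains) > 2)
    stop("expected at most 2 chains (strands), found ", length(chains))
  strand <- match(at$chain, chains) - 1L
  name <- at$elety
  element <- substr(gsub("[^A-Za-z].*$", "", name), 1, 1)
  moiety <- ifelse(name %in% .phosphate_names, "phosphate",
                   ifelse(name %in% .sugar_names, "deoxyribose", "base"))
  atoms <- data.frame(
    element = element, name = name,
    x = at$x, y = at$y, z = at$z,
    nucleotide_index = at$resno - min(at$resno),
    strand = strand, segment_id = segment_id, moiety = moiety,
    stringsAsFactors = FALSE
  )
  n_bp <- length(unique(atoms$nucleotide_index))
  model <- structure(list(atoms = atoms, n_bp = n_bp,
                          topology = topology, form = form),
                     class = "dna_model")
  .check_completeness(model)
  model
}

# warn about nucleotides missing backbone atoms (e.g. a dropped O3')
.check_completeness <- function(model) {
  a <- model$atoms
  key <- paste(a$strand, a$nucleotide_index)
  need_sugar <- .sugar_names
  for (k in unique(key)) {
    nm <- a$name[key == k]
    miss <- setdiff(need_sugar, nm)
    if (length(miss))
      warning("nucleotide (strand ", sub(" .*", "", k), ", index ",
              sub(".* ", "", k), ") is missing backbone atom(s): ",
              paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(model)
}
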