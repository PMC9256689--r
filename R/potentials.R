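# Pair potentials (Morse for covalent bonds, 12-6 Lennard-Jones for
# non-bonded contacts) and the cluster sums that become per-bead
# strand-break threshold energies.

#' Physical constants used throughout the package
#'
#' @format Named numeric vector: `ev_joule` (J per eV), `dyncm_nm`
#'   (N/m per dyn/cm), `water_density` (kg/m^3).
#' @keywords internal
.constants <- c(
  ev_joule = 1.602176634e-19,
  dyncm_nm = 1e-3,
  water_density = 1000
)

#' Bond-stretch and pair-interaction parameter table
#'
#' Equilibrium distances `r_e` (Angstrom), well depths / dissociation
#' energies `D_e` (eV) and bond orders for the element pairs that occur in
#' the DNA backbone. The Morse width `alpha` is always recomputed from the
#' force constant via [alpha_from_force_constant()]; the force constant is
#' set by bond order (5e5, 10e5, 15e5 dyn/cm for single, double, triple
#' bonds). The same rows provide (`r_e`, `D_e`) for the Lennard-Jones form
#' used for non-bonded pairs of the matching elements.
#'
#' @param path optional path to a CSV with columns
#'   `pair_type,r_e,D_e,bond_order` overriding the built-in values.
#' @return data.frame with columns `pair_type`, `r_e`, `D_e`, `bond_order`,
#'   `k_e` (dyn/cm) and `alpha` (1/Angstrom).
#' @export
#' @examples
#' bond_params()
bond_params <- function(path = NULL) {
  if (is.null(path)) {
    tab <- data.frame(
      pair_type  = c("C-C", "C-O", "O-O", "P-O", "P=O"),
      r_e        = c(1.54, 1.43, 1.48, 1.64, 1.50),
      D_e        = c(3.61, 3.73, 1.50, 3.47, 5.64),
      bond_order = c("single", "single", "single", "single", "double"),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("pair_type", "r_e", "D_e", "bond_order")
    if (!all(need %in% names(tab)))
      stop("bond parameter CSV must have columns ",
           paste(need, collapse = ", "))
  }
  tab$k_e <- force_constant(tab$bond_order)
  tab$alpha <- alpha_from_force_constant(tab$k_e, tab$D_e)
  tab
}

#' Force constant implied by bond order
#'
#' @param bond_order character vector: "single", "double" or "triple".
#' @return force constants in dyn/cm (5e5 / 10e5 / 15e5).
#' @export
force_constant <- function(bond_order) {
  k <- c(single = 5e5, double = 10e5, triple = 15e5)[bond_order]
  if (anyNA(k)) stop("unknown bond order: ",
                     paste(unique(bond_order[is.na(k)]), collapse = ", "))
  unname(k)
}

#' Morse width parameter from force constant and well depth
#'
#' Computes `alpha = sqrt(k_e / (2 D_e))` in 1/Angstrom after converting
#' the force constant from dyn/cm to N/m and the dissociation energy from
#' eV to J.
#'
#' @param k_e force constant, dyn/cm.
#' @param D_e dissociation energy (Morse well depth), eV.
#' @return alpha in 1/Angstrom.
#' @export
#' @examples
#' alpha_from_force_constant(5e5, 3.61)  # ~2.08 for a C-C single bond
alpha_from_force_constant <- function(k_e, D_e) {
  if (any(k_e <= 0) || any(D_e <= 0))
    stop("k_e and D_e must be positive")
  k_si <- k_e * .constants[["dyncm_nm"]]        # N/m
  d_si <- D_e * .constants[["ev_joule"]]        # J
  sqrt(k_si / (2 * d_si)) * 1e-10               # 1/m -> 1/Angstrom
}

#' Morse pair energy
#'
#' `U(r) = D_e * (exp(-2 a (r - r_e)) - 2 exp(-a (r - r_e)))`, the standard
#' well form with minimum `-D_e` at `r = r_e` and dissociation limit 0.
#'
#' @param r inter-atomic distance, Angstrom.
#' @param r_e equilibrium bond distance, Angstrom.
#' @param D_e well depth, eV.
#' @param alpha width parameter, 1/Angstrom; if `NULL` it is derived from
#'   `k_e`.
#' @param k_e force constant in dyn/cm (used when `alpha` is `NULL`).
#' @return energy in eV (vectorised over `r`).
#' @export
#' @examples
#' p <- bond_params()
#' po <- p[p$pair_type == "P-O", ]
#' morse_energy(1.480, po$r_e, po$D_e, k_e = po$k_e)  # -2.9038
morse_energy <- function(r, r_e, D_e, alpha = NULL, k_e = NULL) {
  if (any(r <= 0)) stop("r must be positive")
  if (is.null(alpha)) {
    if (is.null(k_e)) stop("supply either alpha or k_e")
    alpha <- alpha_from_force_constant(k_e, D_e)
  }
  D_e * (exp(-2 * alpha * (r - r_e)) - 2 * exp(-alpha * (r - r_e)))
}

#' Lennard-Jones 12-6 pair energy
#'
#' `U(r) = 4 D_e * ((s/r)^12 - (s/r)^6)` with `s = r_e / 2^(1/6)`, so the
#' minimum `-D_e` falls at `r = r_e` and the zero crossing at `r = s`.
#' The (`r_e`, `D_e`) of the matching covalent pair type are reused for
#' non-bonded contacts of the same elements.
#'
#' @param r inter-atomic distance, Angstrom.
#' @param r_e distance of the potential minimum, Angstrom.
#' @param D_e well depth, eV.
#' @return energy in eV (vectorised over `r`).
#' @export
#' @examples
#' oo <- bond_params()[3, ]
#' lj_energy(2.520, oo$r_e, oo$D_e)  # -0.1206
lj_energy <- function(r, r_e, D_e) {
  if (any(r <= 0)) stop("r must be positive")
  s <- r_e / 2^(1 / 6)
  4 * D_e * ((s / r)^12 - (s / r)^6)
}

# --- pair enumeration over a cluster -------------------------------------

#' Covalent bond graph of a standard nucleotide (heavy atoms)
#'
#' Edges are labelled with the pair type used to look up Morse parameters.
#' Includes the two backbone boundary bonds: P-O5' (counted with the
#' phosphate cluster) and C3'-O3' plus C5'-O5' (counted with the
#' deoxyribose cluster).
#'
#' @return data.frame with columns `a`, `b`, `pair_type`.
#' @export
nucleotide_bond_graph <- function() {
  g <- rbind(
    c("P",   "OP1", "P-O"), c("P", "OP2", "P=O"), c("P", "O5'", "P-O"),
    c("C5'", "O5'", "C-O"),
    c("C4'", "C5'", "C-C"), c("C3'", "C4'", "C-C"),
    c("C2'", "C3'", "C-C"), c("C1'", "C2'", "C-C"),
    c("C4'", "O4'", "C-O"), c("C1'", "O4'", "C-O"),
    c("C3'", "O3'", "C-O"),
    c("C1'", "N9",  "C-N"), c("C1'", "N1",  "C-N")  # glycosidic (unused)
  )
  data.frame(a = g[, 1], b = g[, 2], pair_type = g[, 3],
             stringsAsFactors = FALSE)
}

# Atoms of each moiety; O5' belongs to the phosphate, O3' to the sugar.
.phosphate_names <- c("P", "OP1", "OP2", "O5'")
.sugar_names <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'", "O3'")
.base_names <- c("N1", "C2", "N3", "C4", "C5", "C6",
                 "N6", "N7", "C8", "N9", "O2", "O4", "O6", "N2", "N4")

# pair type string for two elements, matching the parameter table rows
.pair_type <- function(ea, eb, bonded_double = FALSE) {
  e <- sort(c(ea, eb))
  if (bonded_double && identical(e, c("O", "P"))) return("P=O")
  paste(e[1], e[2], sep = "-")
}

#' Enumerate bonded and non-bonded pairs of an atom cluster
#'
#' Bonded pairs are covalent bonds internal to the cluster per the
#' standard nucleotide bond graph, plus designated boundary bonds whose
#' second atom is passed in `boundary_atoms` (for the deoxyribose cluster
#' this is O5', contributing the C5'-O5' bond; the phosphate cluster
#' already contains its boundary bond P-O5'). Non-bonded pairs are every
#' remaining pair of cluster atoms.
#'
#' @param atoms data.frame with columns `name`, `element`, `x`, `y`, `z`
#'   (Angstrom) of the cluster atoms.
#' @param boundary_atoms optional data.frame of the same shape whose atoms
#'   contribute only their covalent bond to a cluster atom, not non-bonded
#'   contacts.
#' @param bond_graph covalent bond graph; default [nucleotide_bond_graph()].
#' @return list with data.frames `bonded` and `nonbonded`, each with
#'   columns `a`, `b`, `pair_type`, `r`.
#' @export
enumerate_pairs <- function(atoms, boundary_atoms = NULL,
                            bond_graph = nucleotide_bond_graph()) {
  if (nrow(atoms) == 0) stop("cluster has no atoms")
  known <- unique(c(bond_graph$a, bond_graph$b))
  bad <- setdiff(atoms$name, known)
  # base-ring atoms carry no Morse parameters but are legal cluster members
  bad <- setdiff(bad, .base_names)
  if (length(bad))
    stop("atom(s) absent from the nucleotide bond graph: ",
         paste(bad, collapse = ", "))

  all_atoms <- rbind(atoms[, c("name", "element", "x", "y", "z")],
                     if (!is.null(boundary_atoms))
                       boundary_atoms[, c("name", "element", "x", "y", "z")])
  pos <- as.matrix(all_atoms[, c("x", "y", "z")])
  rownames(pos) <- all_atoms$name
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  graph_keys <- edge_key(bond_graph$a, bond_graph$b)

  bonded <- list(); nonbonded <- list()
  n <- nrow(atoms)
  nm <- atoms$name; el <- atoms$element
  for (i in seq_len(n)) {
    js <- if (i < n) seq(i + 1, n) else integer(0)
    for (j in js) {
      k <- edge_key(nm[i], nm[j])
      r <- sqrt(sum((pos[nm[i], ] - pos[nm[j], ])^2))
      hit <- match(k, graph_keys)
      if (!is.na(hit)) {
        bonded[[length(bonded) + 1L]] <-
          data.frame(a = nm[i], b = nm[j],
                     pair_type = bond_graph$pair_type[hit], r = r)
      } else {
        nonbonded[[length(nonbonded) + 1L]] <-
          data.frame(a = nm[i], b = nm[j],
                     pair_type = .pair_type(el[i], el[j]), r = r)
      }
    }
  }
  # boundary bonds: boundary atom bonded to a cluster atom
  if (!is.null(boundary_atoms) && nrow(boundary_atoms) > 0) {
    for (i in seq_len(nrow(boundary_atoms))) {
      for (j in seq_len(n)) {
        k <- edge_key(boundary_atoms$name[i], nm[j])
        hit <- match(k, graph_keys)
        if (!is.na(hit)) {
          r <- sqrt(sum((pos[boundary_atoms$name[i], ] - pos[nm[j], ])^2))
          bonded[[length(bonded) + 1L]] <-
            data.frame(a = nm[j], b = boundary_atoms$name[i],
                       pair_type = bond_graph$pair_type[hit], r = r)
        }
      }
    }
  }
  list(
    bonded = if (length(bonded)) do.call(rbind, bonded) else
      data.frame(a = character(), b = character(),
                 pair_type = character(), r = numeric()),
    nonbonded = if (length(nonbonded)) do.call(rbind, nonbonded) else
      data.frame(a = character(), b = character(),
                 pair_type = character(), r = numeric())
  )
}

#' Total pair-potential energy of an atom cluster
#'
#' Sums Morse energies over bonded pairs and Lennard-Jones energies over
#' non-bonded pairs at the observed inter-atomic distances. The magnitude
#' of the total is the strand-break threshold energy attached to the
#' corresponding coarse-grained bead. Pairs whose atoms carry no Morse/LJ
#' parameters (base-ring C-N contacts) are not supported and raise an
#' error naming the missing pair type.
#'
#' @inheritParams enumerate_pairs
#' @param params parameter table from [bond_params()].
#' @return object of class `cluster_potential`: list with `pairs`
#'   (per-pair breakdown with columns `a`, `b`, `kind`, `pair_type`, `r`,
#'   `energy`), `U_total` (eV) and `threshold` (`abs(U_total)`, eV).
#' @export
#' @examples
#' tpl <- nucleotide_template()
#' ph <- tpl[tpl$moiety == "phosphate", ]
#' cluster_potential(ph)$U_total  # -12.3562
cluster_potential <- function(atoms, boundary_atoms = NULL,
                              params = bond_params(),
                              bond_graph = nucleotide_bond_graph()) {
  pr <- enumerate_pairs(atoms, boundary_atoms, bond_graph)
  lookup <- function(pt) {
    i <- match(pt, params$pair_type)
    if (anyNA(i))
      stop("no parameters for pair type(s): ",
           paste(unique(pt[is.na(i)]), collapse = ", "))
    params[i, ]
  }
  rows <- list()
  if (nrow(pr$bonded)) {
    p <- lookup(pr$bonded$pair_type)
    e <- morse_energy(pr$bonded$r, p$r_e, p$D_e, alpha = p$alpha)
    rows[[1]] <- cbind(pr$bonded[, c("a", "b", "pair_type", "r")],
                       kind = "bonded", energy = e)
  }
  if (nrow(pr$nonbonded)) {
    p <- lookup(pr$nonbonded$pair_type)
    e <- lj_energy(pr$nonbonded$r, p$r_e, p$D_e)
    rows[[2]] <- cbind(pr$nonbonded[, c("a", "b", "pair_type", "r")],
                       kind = "nonbonded", energy = e)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a = character(), b = character(), pair_type = character(),
               r = numeric(), kind = character(), energy = numeric())
  u <- sum(pairs$energy)
  structure(list(pairs = pairs, U_total = u, threshold = abs(u)),
            class = "cluster_potential")
}

#' @export
print.cluster_potential <- function(x, ...) {
  cat("Cluster pair-potential breakdown\n")
  print(x$pairs, row.names = FALSE, digits = 6)
  cat(sprintf("U_total   %.4f eV\nthreshold %.4f eV\n",
              x$U_total, x$threshold))
  invisible(x)
}

#' Backbone threshold energies of the shipped nucleotide template
#'
#' Convenience wrapper computing the phosphate and deoxyribose cluster
#' potentials of the idealised nucleotide geometry. The deoxyribose
#' cluster includes its two boundary bonds, C3'-O3' (internal, O3' is a
#' sugar atom) and C5'-O5' (O5' enters as a boundary atom).
#'
#' @param params parameter table from [bond_params()].
#' @return named numeric vector `c(phosphate = ..., deoxyribose = ...)`,
#'   threshold energies in eV.
#' @export
#' @examples
#' round(backbone_thresholds(), 1)  # 12.4, 32.3
backbone_thresholds <- function(params = bond_params()) {
  tpl <- nucleotide_template()
  ph <- tpl[tpl$moiety == "phosphate", ]
  su <- tpl[tpl$moiety == "deoxyribose", ]
  o5 <- tpl[tpl$name == "O5'", ]
  c(phosphate = cluster_potential(ph, params = params)$threshold,
    deoxyribose = cluster_potential(su, boundary_atoms = o5,
                                    params = params)$threshold)
}
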