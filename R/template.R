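# Idealised heavy-atom nucleotide template.
#
# The phosphate cluster is embedded exactly from its six published
# pairwise distances (P-OP1 1.480, P=OP2 1.482, P-O5' 1.598, OP1-OP2
# 2.520, OP1-O5' 2.506, OP2-O5' 2.463 Angstrom), so the worked phosphate
# potential reproduces to printed precision. The deoxyribose ring is a
# cyclic pentagon with C-C bonds at 1.54 and C-O bonds at 1.43 Angstrom
# (the equilibrium distances of the parameter table); the base is a
# generic planar purine-like fused ring (base identity does not enter the
# backbone damage model).

.template_env <- new.env(parent = emptyenv())

# rotation matrix taking unit(a) to unit(b) (Rodrigues)
.rotate_ab <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cc <- sum(a * b)
  if (s < 1e-12) {
    if (cc > 0) return(diag(3))
    # 180 degrees: rotate about any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * a) * a; ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - cc) / s^2)
}

# embed a 4-atom cluster from its 6 pairwise distances
.embed_phosphate <- function() {
  dPA <- 1.480; dPB <- 1.482; dPC <- 1.598
  dAB <- 2.520; dAC <- 2.506; dBC <- 2.463
  P <- c(0, 0, 0); A <- c(dPA, 0, 0)
  xB <- (dPB^2 + dPA^2 - dAB^2) / (2 * dPA)
  yB <- sqrt(dPB^2 - xB^2)
  xC <- (dPC^2 + dPA^2 - dAC^2) / (2 * dPA)
  yC <- (dPC^2 - dBC^2 + dPB^2 - 2 * xC * xB) / (2 * yB)
  zC <- sqrt(dPC^2 - xC^2 - yC^2)
  m <- rbind(P, A, c(xB, yB, 0), c(xC, yC, zC))
  rownames(m) <- c("P", "OP1", "OP2", "O5'")
  m
}

.build_template <- function() {
  # deoxyribose ring: cyclic pentagon C1'-C2'-C3'-C4'-O4' with sides
  # 1.54, 1.54, 1.54, 1.43, 1.43; vertices on the circumcircle
  sides <- c(1.54, 1.54, 1.54, 1.43, 1.43)
  f <- function(R) sum(2 * asin(sides / (2 * R))) - 2 * pi
  R <- stats::uniroot(f, c(max(sides) / 2 + 1e-9, 10), tol = 1e-12)$root
  ang <- cumsum(c(0, 2 * asin(sides / (2 * R))))[1:5]
  ring <- cbind(R * cos(ang), R * sin(ang), 0)
  rownames(ring) <- c("C1'", "C2'", "C3'", "C4'", "O4'")

  outward <- function(i) c(ring[i, 1:2] / sqrt(sum(ring[i, 1:2]^2)), 0)
  s70 <- sin(70 * pi / 180); c70 <- cos(70 * pi / 180)
  C5p <- ring["C4'", ] + 1.54 * (outward(4) * s70 + c(0, 0, c70))
  O3p <- ring["C3'", ] + 1.43 * (outward(3) * s70 - c(0, 0, c70))
  s50 <- sin(50 * pi / 180); c50 <- cos(50 * pi / 180)
  dirO5 <- outward(4) * s50 + c(0, 0, c50)
  O5p <- C5p + 1.43 * dirO5

  # rigidly place the exact phosphate so its O5' lands on O5p with the
  # O5'->P direction continuing away from the sugar
  ph <- .embed_phosphate()
  rot <- .rotate_ab(ph["P", ] - ph["O5'", ], dirO5)
  ph <- t(rot %*% t(sweep(ph, 2, ph["O5'", ]))) +
    matrix(O5p, 4, 3, byrow = TRUE)

  # generic purine-like base: hexagon (side 1.39) fused with a pentagon,
  # plus one exocyclic N; attached to C1' opposite the sugar ring centre
  hex <- t(sapply(0:5, function(k)
    1.39 * c(cos(pi / 3 * k + pi / 6), sin(pi / 3 * k + pi / 6), 0)))
  rownames(hex) <- c("C5", "C6", "N1", "C2", "N3", "C4")
  C4b <- hex["C4", ]; C5b <- hex["C5", ]
  mid <- (C4b + C5b) / 2; edge <- C5b - C4b
  eL <- sqrt(sum(edge^2))
  perp <- c(edge[2], -edge[1], 0) / eL
  Rp <- eL / (2 * sin(pi / 5)); apo <- Rp * cos(pi / 5)
  ctr <- mid + perp * apo
  if (sqrt(sum(ctr[1:2]^2)) < 1.2) ctr <- mid - perp * apo
  angC4 <- atan2(C4b[2] - ctr[2], C4b[1] - ctr[1])
  angC5 <- atan2(C5b[2] - ctr[2], C5b[1] - ctr[1])
  dd <- (angC4 - angC5) %% (2 * pi)
  step <- if (dd < pi) 2 * pi / 5 else -2 * pi / 5
  pent <- function(k) ctr + Rp * c(cos(angC4 + k * step),
                                   sin(angC4 + k * step), 0)
  base <- rbind(hex, "N9" = pent(1), "C8" = pent(2), "N7" = pent(3),
                "N6" = hex["C6", ] +
                  1.34 * hex["C6", ] / sqrt(sum(hex["C6", ]^2)))

  # orient base: glycosidic N9 at 1.47 A from C1', ring extending away
  # from the sugar ring centre, tilted out of the sugar plane
  gdir <- -outward(1) * s70 + c(0, 0, c70) * 0.3
  gdir <- gdir / sqrt(sum(gdir^2))
  N9_target <- ring["C1'", ] + 1.47 * gdir
  rot2 <- .rotate_ab(c(-1, 0, 0), gdir)
  base <- t(rot2 %*% t(sweep(base, 2, base["N9", ]))) +
    matrix(N9_target, nrow(base), 3, byrow = TRUE)

  coords <- rbind(ph, ring, "C5'" = C5p, "O3'" = O3p, base)
  nm <- rownames(coords)
  moiety <- ifelse(nm %in% .phosphate_names, "phosphate",
                   ifelse(nm %in% .sugar_names, "deoxyribose", "base"))
  el <- substr(gsub("[^A-Za-z].*$", "", nm), 1, 1)
  out <- data.frame(name = nm, element = el,
                    x = coords[, 1], y = coords[, 2], z = coords[, 3],
                    moiety = moiety, stringsAsFactors = FALSE,
                    row.names = NULL)
  # canonical frame for helix assembly: C1' at origin, base pointing
  # along -x (toward the helix axis), backbone along +x
  c1 <- unlist(out[out$name == "C1'", c("x", "y", "z")])
  out[, c("x", "y", "z")] <- sweep(out[, c("x", "y", "z")], 2, c1)
  bdir <- colMeans(out[out$moiety == "base", c("x", "y", "z")])
  rot3 <- .rotate_ab(as.numeric(bdir), c(-1, 0, 0))
  out[, c("x", "y", "z")] <- t(rot3 %*% t(as.matrix(out[, c("x", "y", "z")])))
  out
}

#' Idealised heavy-atom nucleotide template
#'
#' Coordinates (Angstrom) of the 21 heavy atoms of one generic nucleotide
#' in a local frame with C1' at the origin and the base extending along
#' -x. The phosphate cluster geometry is fixed by its six published
#' pairwise distances; sugar bonds sit at the equilibrium distances of
#' [bond_params()].
#'
#' @return data.frame with columns `name`, `element`, `x`, `y`, `z`,
#'   `moiety`.
#' @export
nucleotide_template <- function() {
  if (is.null(.template_env$tpl)) .template_env$tpl <- .build_template()
  .template_env$tpl
}
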