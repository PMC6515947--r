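# Mapping epitope zones onto a 3D structure and classifying residues into
# the two faces (L and J) of the open fish-hook conformation.
#
# The faces are defined reproducibly rather than by manual rotation in a
# viewer: a least-squares reference plane is fitted through all alpha
# carbons and oriented so that a set of anchor residues (by default the
# D1 epitope residues 39-43, known to sit on the L side) has positive mean
# signed distance. Residues within edge_delta of the plane are "edge".

#' Read alpha-carbon coordinates from a PDB structure
#'
#' Parses ATOM records (via bio3d), keeps one CA per residue (first altloc
#' wins), and records which residue numbers are resolved. Insertion codes
#' are not supported and raise an error.
#'
#' @param pdb path to a PDB file, or a `bio3d` pdb object.
#' @param chain chain identifier; default takes the first chain present.
#' @return data.frame of class `"structure_model"`: `resno`, `x`, `y`, `z`,
#'   with attributes `chain` and `unresolved` (residue numbers missing
#'   between the observed min and max).
#' @export
read_structure <- function(pdb, chain = NULL) {
  if (is.character(pdb)) {
    # bio3d warns while resolving altlocs (it keeps the first, as we want)
    pdb <- suppressWarnings(bio3d::read.pdb(pdb, verbose = FALSE))
  }
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (!nrow(at)) pz_stop("no_such_chain", sprintf("no CA atoms in chain '%s'", chain))
  if (any(!is.na(at$insert) & nzchar(at$insert))) {
    pz_stop("bad_structure", "insertion codes are not supported")
  }
  at <- at[!duplicated(at$resno), , drop = FALSE]  # first altloc wins
  if (!nrow(at)) pz_stop("no_atoms", "no atoms after filtering")
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    pz_stop("bad_structure", "non-finite coordinates")
  }
  model <- data.frame(resno = at$resno, x = at$x, y = at$y, z = at$z)
  model <- model[order(model$resno), , drop = FALSE]
  rownames(model) <- NULL
  attr(model, "chain") <- chain
  attr(model, "unresolved") <- setdiff(seq(min(model$resno), max(model$resno)),
                                       model$resno)
  class(model) <- c("structure_model", class(model))
  model
}

#' Fit the face-defining reference plane
#'
#' Least-squares plane through all alpha carbons: the plane through the
#' centroid whose normal is the direction of least coordinate variance
#' (third principal component). The normal is oriented so the anchor
#' residues' mean signed distance is positive; that side is face L.
#'
#' @param model a [read_structure()] model.
#' @param anchors residue numbers fixing the L side (default 39:43, the
#'   domain-1 epitope).
#' @param edge_delta half-width in Angstrom of the "edge" band around the
#'   plane (default 1.5).
#' @return object of class `"face_plane"`: unit `normal`, `centroid`,
#'   `offset` (= normal . centroid), `anchors`, `edge_delta`.
#' @export
fit_face_plane <- function(model, anchors = 39:43, edge_delta = 1.5) {
  xyz <- as.matrix(model[, c("x", "y", "z")])
  if (nrow(xyz) < 4L) pz_stop("degenerate_geometry", "need >= 4 residues")
  if (!all(anchors %in% model$resno)) {
    pz_stop("degenerate_geometry", "anchor residues not resolved in the model")
  }
  pc <- stats::prcomp(xyz, center = TRUE, scale. = FALSE)
  if (pc$sdev[2] < 1e-8) {
    pz_stop("degenerate_geometry", "coordinates are collinear; no unique plane")
  }
  normal <- unname(pc$rotation[, 3L])
  normal <- normal / sqrt(sum(normal^2))
  centroid <- colMeans(xyz)
  sd_anchor <- mean((as.matrix(model[model$resno %in% anchors, c("x", "y", "z")]) -
                       matrix(centroid, sum(model$resno %in% anchors), 3,
                              byrow = TRUE)) %*% normal)
  if (abs(sd_anchor) < edge_delta) {
    pz_stop("anchors_on_plane",
            "anchor residues lie within the edge band; cannot orient the plane")
  }
  if (sd_anchor < 0) normal <- -normal
  structure(list(normal = normal, centroid = centroid,
                 offset = sum(normal * centroid),
                 anchors = anchors, edge_delta = edge_delta),
            class = "face_plane")
}

#' @export
print.face_plane <- function(x, ...) {
  cat(sprintf("<face_plane> normal = (%.3f, %.3f, %.3f), edge band +/- %.2f A\n",
              x$normal[1], x$normal[2], x$normal[3], x$edge_delta))
  cat(sprintf("  oriented by anchors %s (positive side = L)\n",
              paste(range(x$anchors), collapse = "-")))
  invisible(x)
}

#' Signed distance of each residue from the reference plane
#' @noRd
signed_distance <- function(model, plane) {
  xyz <- as.matrix(model[, c("x", "y", "z")])
  as.numeric(xyz %*% plane$normal) - plane$offset
}

#' Classify residues into the L and J faces
#'
#' Signed-distance rule: `L` beyond `+edge_delta`, `J` beyond
#' `-edge_delta`, `edge` within the band. The band absorbs side-chain
#' protrusions that can make a residue look as if it sat on the wrong face
#' in a rendered view.
#'
#' @param model a [read_structure()] model.
#' @param plane a [fit_face_plane()] plane.
#' @return character vector (`"L"`, `"J"`, `"edge"`) named by residue
#'   number.
#' @export
classify_faces <- function(model, plane) {
  stopifnot(inherits(plane, "face_plane"))
  d <- signed_distance(model, plane)
  lab <- ifelse(d > plane$edge_delta, "L",
                ifelse(d < -plane$edge_delta, "J", "edge"))
  stats::setNames(lab, model$resno)
}

#' Face composition of epitope zones
#'
#' Fraction of each zone's resolved residues on face L, face J and the
#' edge band. Unresolved residues are excluded from denominators and
#' counted in `n_unresolved`.
#'
#' @param zones data.frame with `zone`, `span_start`, `span_end` (residue
#'   coordinates, as produced by [detect_zones()] with a peptide table).
#' @param labels residue face labels from [classify_faces()].
#' @return data.frame: `zone`, `n_resolved`, `n_unresolved`, `frac_L`,
#'   `frac_J`, `frac_edge`, `majority`.
#' @export
zone_face_fraction <- function(zones, labels) {
  resno <- as.integer(names(labels))
  out <- lapply(seq_len(nrow(zones)), function(i) {
    span <- zones$span_start[i]:zones$span_end[i]
    inz <- labels[resno %in% span]
    if (!length(inz)) {
      pz_stop("empty_zone", sprintf("zone %s has no resolved residues",
                                    zones$zone[i]))
    }
    fr <- c(L = mean(inz == "L"), J = mean(inz == "J"), edge = mean(inz == "edge"))
    data.frame(zone = zones$zone[i],
               n_resolved = length(inz),
               n_unresolved = length(span) - length(inz),
               frac_L = fr[["L"]], frac_J = fr[["J"]], frac_edge = fr[["edge"]],
               majority = names(which.max(fr)))
  })
  do.call(rbind, out)
}

#' Export face labels as a PDB B-factor overlay
#'
#' Writes the model with B-factors encoding the face (`L = 1`, `J = -1`,
#' `edge = 0`) so any structure viewer can color the faces.
#'
#' @param model a [read_structure()] model.
#' @param labels labels from [classify_faces()].
#' @param path output PDB path.
#' @export
write_face_overlay <- function(model, labels, path) {
  n <- nrow(model)
  b <- unname(c(L = 1, J = -1, edge = 0)[labels[as.character(model$resno)]])
  xyz <- as.numeric(t(as.matrix(model[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = model$resno,
                   chain = rep(attr(model, "chain") %||% "A", n),
                   resid = rep("ALA", n), elety = rep("CA", n),
                   eleno = seq_len(n), o = rep(1, n), b = b)
  invisible(path)
}
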