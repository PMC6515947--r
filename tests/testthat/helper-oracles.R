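# Independent brute-force oracles and tiny fixture builders shared across
# the suite. Oracles deliberately avoid the package's own code paths.

# all start positions of motif in seq by exhaustive substring comparison
brute_motif <- function(seq, motif) {
  s <- as.character(seq)
  n <- nchar(s); m <- nchar(motif)
  hits <- integer()
  if (m > n) return(hits)
  for (i in seq_len(n - m + 1L)) {
    if (substr(s, i, i + m - 1L) == motif) hits <- c(hits, i)
  }
  hits
}

# per-spot sum by explicit double loop over every pixel
brute_iod <- function(image, row0, col0, radius) {
  total <- 0
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      if ((i - row0)^2 + (j - col0)^2 <= radius^2) total <- total + image[i, j]
    }
  }
  total
}

# maximal supra-threshold runs by scanning every contiguous interval
brute_zones <- function(p, threshold) {
  n <- length(p)
  runs <- list()
  for (a in seq_len(n)) {
    for (b in a:n) {
      if (all(p[a:b] >= threshold) &&
          (a == 1L || p[a - 1L] < threshold) &&
          (b == n || p[b + 1L] < threshold)) {
        runs[[length(runs) + 1L]] <-
          c(first = a, last = b, rep = a + which.max(p[a:b]) - 1L)
      }
    }
  }
  if (!length(runs)) {
    return(data.frame(first = integer(), last = integer(), rep = integer()))
  }
  as.data.frame(do.call(rbind, runs))
}

# fixed-circle quants built directly (no image), for threshold/call tests
quants_fixture <- function(neg, pep) {
  data.frame(
    spot_id = c(sprintf("NEG%d", seq_along(neg)), sprintf("P%02d", seq_along(pep))),
    role = rep(c("negative", "peptide"), c(length(neg), length(pep))),
    peptide = c(rep(NA_integer_, length(neg)), seq_along(pep)),
    iod = c(neg, pep),
    stringsAsFactors = FALSE
  )
}

# 3D rotation matrix about a unit axis
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle); s0 <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) * c0 + s0 * K + (1 - c0) * (a %o% a)
}

apply_rigid <- function(model, R, shift) {
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(R)
  out <- model
  out$x <- xyz[, 1] + shift[1]
  out$y <- xyz[, 2] + shift[2]
  out$z <- xyz[, 3] + shift[3]
  out
}

# minimal PDB writer for read_structure fixtures (fixed-column ATOM records)
pdb_line <- function(serial, resno, x, y, z, altloc = " ", chain = "A",
                     icode = " ", name = " CA ") {
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, altloc, "ALA", chain, resno, icode, x, y, z, 1, 0)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# write a structure_model out as a PDB file (for pipeline tests)
model_to_pdb <- function(model, path = tempfile(fileext = ".pdb")) {
  lines <- vapply(seq_len(nrow(model)), function(i) {
    pdb_line(i, model$resno[i], model$x[i], model$y[i], model$z[i])
  }, character(1))
  write_pdb_fixture(lines, path)
}

# balanced planted spans used by structure tests: the three epitope zones
# plus the D1 anchor on L, mirrored-size control spans on J
L_SPANS <- list(c(39, 43), c(129, 151), c(181, 219), c(245, 279))
J_SPANS <- list(c(55, 59), c(85, 107), c(155, 177), c(285, 319))
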