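# Sequence-level operations: peptide-table IO, antigen reconstruction,
# overlapping-peptide tiling, domain annotation, motif search.
#
# All residue coordinates are 1-based and inclusive, matching how pepscan
# peptide tables are printed. Conversion to 0-based half-open happens only at
# BED export, never internally.

#' Read an overlapping-peptide table
#'
#' Reads a pepscan design table with one row per synthesized peptide. The
#' package ships the 79-peptide B2GP1 design as
#' `pepzone_extdata("peptide_table.tsv")`, which is also the default.
#'
#' @param path TSV file with columns `peptide_number`, `sequence`, `start`,
#'   `end`, `domain` (start/end 1-based inclusive residue coordinates on the
#'   mature antigen).
#' @return a `data.frame` with those five columns, ordered by `start`.
#' @examples
#' peps <- read_peptide_table()
#' head(peps)
#' @export
read_peptide_table <- function(path = pepzone_extdata("peptide_table.tsv")) {
  df <- pz_read_tsv(path)
  required <- c("peptide_number", "sequence", "start", "end", "domain")
  if (!all(required %in% names(df))) {
    pz_stop("bad_table", sprintf(
      "peptide table must have columns %s", paste(required, collapse = ", ")
    ))
  }
  df$peptide_number <- as.integer(df$peptide_number)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$domain <- as.character(df$domain)
  df$sequence <- toupper(as.character(df$sequence))
  validate_peptides(df)
  df[order(df$start), , drop = FALSE]
}

validate_peptides <- function(peptides) {
  stopifnot(is.data.frame(peptides), nrow(peptides) >= 1L)
  if (any(peptides$end - peptides$start + 1L != nchar(peptides$sequence))) {
    pz_stop("bad_table", "peptide span length disagrees with sequence length")
  }
  bad <- setdiff(unique(strsplit(paste(peptides$sequence, collapse = ""), "")[[1]]),
                 AA_ALPHABET)
  if (length(bad)) {
    pz_stop("bad_table", sprintf("non amino-acid characters: %s",
                                 paste(bad, collapse = "")))
  }
  invisible(peptides)
}

#' Reconstruct the antigen sequence from overlapping peptides
#'
#' Stitches overlapping peptides back into the unique protein sequence they
#' tile. Every residue covered by two or more peptides must agree
#' character-by-character, which doubles as an integrity check on the printed
#' table: a single typo inside an overlap raises an `overlap_conflict` error.
#'
#' @param peptides peptide table as from [read_peptide_table()].
#' @param id sequence identifier attached to the result.
#' @return a character scalar (the residue string) with attribute `id`,
#'   classed `"protein_seq"`.
#' @examples
#' seq <- stitch_peptides(read_peptide_table())
#' nchar(seq)  # 326 for the mature B2GP1 chain
#' @export
stitch_peptides <- function(peptides, id = "B2GP1") {
  validate_peptides(peptides)
  peptides <- peptides[order(peptides$start), , drop = FALSE]
  len <- max(peptides$end)
  residues <- rep(NA_character_, len)
  for (i in seq_len(nrow(peptides))) {
    pos <- peptides$start[i]:peptides$end[i]
    chars <- strsplit(peptides$sequence[i], "")[[1]]
    seen <- !is.na(residues[pos])
    if (any(seen & residues[pos] != chars)) {
      at <- pos[seen & residues[pos] != chars][1]
      pz_stop("overlap_conflict", sprintf(
        "peptide %s disagrees with earlier peptides at residue %d",
        peptides$peptide_number[i], at
      ), residue = at)
    }
    residues[pos] <- chars
  }
  if (anyNA(residues)) {
    gap <- which(is.na(residues))[1]
    pz_stop("coverage_gap",
            sprintf("no peptide covers residue %d", gap), residue = gap)
  }
  structure(paste(residues, collapse = ""), id = id, class = "protein_seq")
}

#' @export
print.protein_seq <- function(x, ...) {
  cat(sprintf("<protein_seq> %s: %d aa\n", attr(x, "id"), nchar(x)))
  cat(strwrap(unclass(x), width = 60), sep = "\n")
  invisible(x)
}

#' Tiling configuration for overlapping-peptide design
#'
#' @param window_len peptide length in residues (default 15).
#' @param step residues between successive peptide starts (default 4, i.e.
#'   an 11-residue overlap for 15-mers).
#' @param anchor_final if `TRUE` (default) and the next regular window would
#'   run past the C-terminus, one final window anchored to end at the last
#'   residue is emitted, so the terminus is always covered.
#' @return a list of class `"tiling_config"`.
#' @export
tiling_config <- function(window_len = 15L, step = 4L, anchor_final = TRUE) {
  window_len <- as.integer(window_len)
  step <- as.integer(step)
  if (step < 1L || step > window_len) {
    pz_stop("bad_config", "need 1 <= step <= window_len")
  }
  structure(list(window_len = window_len, step = step,
                 anchor_final = isTRUE(anchor_final)),
            class = "tiling_config")
}

#' Tile a protein into overlapping peptides
#'
#' Generates the pepscan design: peptide `i` spans
#' `step*(i-1)+1 ... step*(i-1)+window_len`. When the next regular window
#' would overrun the C-terminus and `anchor_final` is set, a single final
#' window ending exactly at the last residue is added (its overlap with the
#' previous peptide exceeds the regular one). With the default 15/4
#' configuration the 326-residue mature B2GP1 yields 79 peptides, the last
#' spanning 312-326.
#'
#' @param seq a `protein_seq` or plain character scalar.
#' @param cfg a [tiling_config()].
#' @return peptide `data.frame` (`peptide_number`, `sequence`, `start`,
#'   `end`) ready for [annotate_domains()].
#' @examples
#' tile_protein(stitch_peptides(read_peptide_table()))[c(1, 79), ]
#' @export
tile_protein <- function(seq, cfg = tiling_config()) {
  stopifnot(inherits(cfg, "tiling_config"))
  s <- as.character(seq)
  len <- nchar(s)
  w <- cfg$window_len
  if (len < w) {
    pz_stop("sequence_too_short",
            sprintf("sequence of %d aa is shorter than the %d aa window", len, w))
  }
  starts <- seq.int(1L, len - w + 1L, by = cfg$step)
  last_end <- starts[length(starts)] + w - 1L
  if (cfg$anchor_final && last_end < len) {
    starts <- c(starts, len - w + 1L)
  }
  ends <- starts + w - 1L
  data.frame(
    peptide_number = seq_along(starts),
    sequence = substring(s, starts, ends),
    start = starts,
    end = ends,
    stringsAsFactors = FALSE
  )
}

#' Domain map for a multi-domain antigen
#'
#' The five sushi domains of mature B2GP1 are delimited by the last residue
#' of each domain. The defaults `(61, 120, 183, 243, 326)` are each drawn
#' from the boundary ranges consistent with the printed per-peptide domain
#' labels (see [infer_domain_boundaries()]).
#'
#' @param domain_ends strictly increasing residue indices; the last entry is
#'   the protein length.
#' @export
domain_map <- function(domain_ends = c(61L, 120L, 183L, 243L, 326L)) {
  domain_ends <- as.integer(domain_ends)
  if (is.unsorted(domain_ends, strictly = TRUE)) {
    pz_stop("bad_config", "domain_ends must be strictly increasing")
  }
  structure(list(domain_ends = domain_ends), class = "domain_map")
}

residue_domain <- function(pos, dmap) {
  # domain of a residue = first domain whose end is >= pos
  findInterval(pos - 1L, dmap$domain_ends) + 1L
}

#' Annotate peptides with domain labels
#'
#' A peptide lying entirely inside one domain gets that domain's number; a
#' peptide crossing exactly one boundary gets the spanning label `"k-k+1"`.
#' Crossing two or more boundaries (impossible when the window is shorter
#' than the shortest domain) is an error.
#'
#' @param peptides peptide table (needs `start`, `end`).
#' @param dmap a [domain_map()].
#' @return the table with a `domain` character column added/replaced.
#' @examples
#' tiled <- tile_protein(stitch_peptides(read_peptide_table()))
#' annotate_domains(tiled)[c(11, 14, 79), ]
#' @export
annotate_domains <- function(peptides, dmap = domain_map()) {
  stopifnot(inherits(dmap, "domain_map"))
  last <- dmap$domain_ends[length(dmap$domain_ends)]
  if (any(peptides$end > last)) {
    pz_stop("unmapped_span", "peptide extends beyond the last domain end")
  }
  d1 <- residue_domain(peptides$start, dmap)
  d2 <- residue_domain(peptides$end, dmap)
  if (any(d2 - d1 > 1L)) {
    pz_stop("unmapped_span", "a peptide crosses more than one domain boundary")
  }
  peptides$domain <- ifelse(d1 == d2, as.character(d1), paste0(d1, "-", d2))
  peptides
}

#' Locate exact occurrences of a motif
#'
#' Exact (overlap-allowing) matches of a short amino-acid motif in the
#' antigen, e.g. the hexapeptides targeted by the pathogenic monoclonals
#' H-3 (`TLRVYK`, residue 133) and ILA-3 (`KDKATF`, residue 208).
#'
#' @param seq protein sequence (character or `protein_seq`).
#' @param motif amino-acid string, non-empty.
#' @return integer vector of 1-based start positions (possibly empty).
#' @examples
#' seq <- stitch_peptides(read_peptide_table())
#' find_motif(seq, "TLRVYK")
#' @export
find_motif <- function(seq, motif) {
  motif <- as.character(motif)
  if (!nzchar(motif)) pz_stop("empty_motif", "motif must be non-empty")
  s <- Biostrings::AAString(as.character(seq))
  m <- Biostrings::matchPattern(Biostrings::AAString(toupper(motif)), s)
  as.integer(Biostrings::start(m))
}

#' Residue midpoint of a peptide span
#'
#' Arithmetic midpoint of the 1-based inclusive span; exact for odd window
#' lengths, rounded down for even spans. Peptide 34 of the B2GP1 design
#' (133-147) has midpoint 140, the printed center of the first
#' high-antigenicity zone.
#'
#' @param start,end 1-based inclusive residue coordinates (vectorized), or a
#'   peptide table row via `peptide_midpoint(peptides)`.
#' @return integer midpoints.
#' @export
peptide_midpoint <- function(start, end = NULL) {
  if (is.data.frame(start)) {
    end <- start$end
    start <- start$start
  }
  if (any(end < start)) pz_stop("bad_table", "end < start")
  as.integer((as.integer(start) + as.integer(end)) %/% 2L)
}

#' Infer feasible domain boundaries from peptide labels
#'
#' Given peptides annotated with single-domain and spanning (`"k-k+1"`)
#' labels, intersects the constraints each label places on the last residue
#' of each domain: a peptide labelled `k` forces the boundary at or after
#' its end (and the previous boundary before its start); a spanning peptide
#' forces the boundary strictly inside its span.
#'
#' @param annotated peptide table with a `domain` column.
#' @return data.frame with one row per adjacent domain pair: `left_domain`,
#'   `lo`, `hi` — the inclusive feasible range for the last residue of
#'   `left_domain`.
#' @export
infer_domain_boundaries <- function(annotated) {
  lab <- annotated$domain
  single <- grepl("^[0-9]+$", lab)
  doms <- sort(unique(as.integer(lab[single])))
  out <- data.frame(left_domain = integer(), lo = integer(), hi = integer())
  for (k in doms[-length(doms)]) {
    lo <- 1L
    hi <- max(annotated$end)
    # peptides fully in k: boundary >= their end
    in_k <- lab == as.character(k)
    if (any(in_k)) lo <- max(lo, max(annotated$end[in_k]))
    # peptides fully in k+1: boundary <= their start - 1
    in_k1 <- lab == as.character(k + 1L)
    if (any(in_k1)) hi <- min(hi, min(annotated$start[in_k1]) - 1L)
    # spanning peptides: start <= boundary <= end - 1
    sp <- lab == paste0(k, "-", k + 1L)
    if (any(sp)) {
      lo <- max(lo, max(annotated$start[sp]))
      hi <- min(hi, min(annotated$end[sp]) - 1L)
    }
    if (lo > hi) {
      pz_stop("inconsistent_labels", sprintf(
        "no boundary between domains %d and %d satisfies all labels", k, k + 1L
      ))
    }
    out <- rbind(out, data.frame(left_domain = k, lo = lo, hi = hi))
  }
  out
}

#' Write the antigen as FASTA
#'
#' @param seq a `protein_seq` or character scalar.
#' @param path output file.
#' @param id FASTA record name; defaults to the sequence's own id.
#' @export
write_antigen_fasta <- function(seq, path, id = attr(seq, "id") %||% "antigen") {
  set <- Biostrings::AAStringSet(as.character(seq))
  names(set) <- id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a tiling as TSV or BED-like intervals
#'
#' The TSV keeps the package's 1-based inclusive coordinates. The BED export
#' converts to 0-based half-open at write time only and says so in its
#' header comment.
#'
#' @param peptides peptide table.
#' @param path output file.
#' @export
write_tiling_tsv <- function(peptides, path) {
  pz_write_tsv(peptides, path)
}

#' @rdname write_tiling_tsv
#' @param chrom name used in the BED chrom column.
#' @export
write_tiling_bed <- function(peptides, path, chrom = "B2GP1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED-like export: coordinates converted to 0-based half-open", con)
  bed <- data.frame(chrom = chrom,
                    start = peptides$start - 1L,
                    end = peptides$end,
                    name = paste0("P", peptides$peptide_number))
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
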