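# Per-peptide antigenicity profiles, high-antigenicity zone detection and
# per-serum breadth summaries.

#' Construct a serum x peptide reactivity matrix
#'
#' @param calls binary/logical matrix, one row per serum, one column per
#'   peptide (columns in peptide order). No missing cells; all-zero sera
#'   (non-reactive on the whole array) are legitimate and retained.
#' @param group optional per-serum group labels (e.g. CKD / NKF /
#'   asymptomatic), recycled checking length.
#' @return integer 0/1 matrix of class `"reactivity_matrix"` with a
#'   `group` attribute.
#' @export
reactivity_matrix <- function(calls, group = NULL) {
  m <- as.matrix(calls)
  if (anyNA(m)) pz_stop("bad_matrix", "reactivity matrix has missing cells")
  if (!all(m %in% c(0, 1))) pz_stop("bad_matrix", "calls must be binary")
  storage.mode(m) <- "integer"
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("P", seq_len(ncol(m)))
  if (!is.null(group)) {
    if (length(group) != nrow(m)) pz_stop("bad_matrix", "one group label per serum")
    attr(m, "group") <- as.character(group)
  }
  class(m) <- c("reactivity_matrix", class(m))
  m
}

#' Per-peptide recognition frequency
#'
#' Fraction of sera recognizing each peptide. Sera that recognized nothing
#' stay in the denominator, matching how cohort-wide percentages are
#' reported.
#'
#' @param m a [reactivity_matrix()].
#' @return numeric vector of fractions in `[0,1]`, one per peptide, with
#'   attribute `n_sera`; class `"antigenicity_profile"`.
#' @export
recognition_frequency <- function(m) {
  if (!is.matrix(m) || nrow(m) < 1L) pz_stop("empty_matrix", "need at least one serum")
  p <- colMeans(unclass(m))
  structure(p, n_sera = nrow(m), class = "antigenicity_profile")
}

#' Detect contiguous high-antigenicity zones
#'
#' A peptide is highly antigenic when its recognition fraction is at or
#' above `threshold` (default 50% of sera). A zone is a maximal run of
#' consecutive highly antigenic peptides; its representative is the most
#' recognized member (ties break to the lowest peptide index).
#'
#' @param profile an [recognition_frequency()] profile (or plain numeric
#'   vector of fractions).
#' @param threshold recognition fraction required (default 0.5).
#' @param peptides optional peptide table (as from [annotate_domains()]);
#'   when given, residue spans, representative midpoints and covered domain
#'   labels are attached.
#' @return data.frame with one row per zone: `zone`, `first_pep`,
#'   `last_pep`, `representative`, and with `peptides` also
#'   `rep_midpoint`, `span_start`, `span_end`, `domains`.
#' @examples
#' p <- c(rep(0.2, 32), 0.6, 0.8, 0.55, rep(0.2, 44))
#' detect_zones(p)
#' @export
detect_zones <- function(profile, threshold = 0.5, peptides = NULL) {
  p <- as.numeric(profile)
  hi <- p >= threshold
  if (!any(hi)) {
    zones <- data.frame(zone = integer(), first_pep = integer(),
                        last_pep = integer(), representative = integer())
  } else {
    r <- rle(hi)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    starts <- starts[keep]; ends <- ends[keep]
    rep_idx <- mapply(function(a, b) a + which.max(p[a:b]) - 1L, starts, ends)
    zones <- data.frame(zone = seq_along(starts), first_pep = starts,
                        last_pep = ends, representative = as.integer(rep_idx))
  }
  if (!is.null(peptides) && nrow(zones)) {
    stopifnot(all(zones$last_pep <= nrow(peptides)))
    zones$rep_midpoint <- peptide_midpoint(peptides[zones$representative, ])
    zones$span_start <- peptides$start[zones$first_pep]
    zones$span_end <- peptides$end[zones$last_pep]
    if (!is.null(peptides$domain)) {
      zones$domains <- vapply(seq_len(nrow(zones)), function(i) {
        labs <- peptides$domain[zones$first_pep[i]:zones$last_pep[i]]
        paste(unique(unlist(strsplit(labs, "-"))), collapse = ",")
      }, character(1))
    }
  }
  zones
}

#' Report peptides just below the antigenicity cutoff
#'
#' Peptides with recognition in `[low, threshold)` — the "zone 4"-style
#' near-misses, such as a peptide recognized by 46% of sera under a 50%
#' cutoff.
#'
#' @param profile recognition fractions.
#' @param low lower bound (default 0.45).
#' @param threshold the zone cutoff (default 0.5); must exceed `low`.
#' @return integer vector of peptide indices.
#' @export
near_threshold_report <- function(profile, low = 0.45, threshold = 0.5) {
  if (!(low < threshold)) pz_stop("bad_config", "need low < threshold")
  p <- as.numeric(profile)
  which(p >= low & p < threshold)
}

#' Per-serum breadth of recognition
#'
#' Number of peptides each serum recognizes, with group means when the
#' matrix carries group labels.
#'
#' @param m a [reactivity_matrix()].
#' @return list with `per_serum` (named integer vector) and `group_means`
#'   (named numeric vector, or overall mean under the name "all").
#' @export
serum_breadth <- function(m) {
  counts <- rowSums(unclass(m))
  group <- attr(m, "group")
  if (is.null(group)) {
    means <- c(all = mean(counts))
  } else {
    means <- tapply(counts, group, mean)
    means <- stats::setNames(as.numeric(means), names(means))
  }
  list(per_serum = counts, group_means = means)
}

#' Write / read a reactivity matrix as TSV
#'
#' Sera are rows; the first two columns are `serum_id` and `group`.
#' @param m a [reactivity_matrix()].
#' @param path TSV path.
#' @export
write_reactivity_tsv <- function(m, path) {
  df <- data.frame(serum_id = rownames(m),
                   group = attr(m, "group") %||% NA_character_,
                   unclass(m), check.names = FALSE)
  pz_write_tsv(df, path)
}

#' @rdname write_reactivity_tsv
#' @export
read_reactivity_tsv <- function(path) {
  df <- pz_read_tsv(path, check.names = FALSE)
  calls <- as.matrix(df[, setdiff(names(df), c("serum_id", "group")), drop = FALSE])
  rownames(calls) <- df$serum_id
  group <- if (all(is.na(df$group))) NULL else df$group
  reactivity_matrix(calls, group = group)
}

#' Bar plot of an antigenicity profile
#'
#' Per-peptide recognition percentages with the zone cutoff drawn as a
#' horizontal line; base graphics.
#'
#' @param profile recognition fractions.
#' @param threshold cutoff drawn on the plot.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_antigenicity <- function(profile, threshold = 0.5, ...) {
  p <- as.numeric(profile) * 100
  graphics::barplot(p, names.arg = seq_along(p), las = 2, cex.names = 0.5,
                    ylab = "% sera positive", xlab = "peptide", ...)
  graphics::abline(h = threshold * 100, lty = 2)
  invisible(profile)
}
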