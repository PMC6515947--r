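# Seed-deterministic synthetic-data generators. These emulate the
# statistical structure the analysis assumes -- per-serum binary peptide
# reactivity with zone enrichment, a two-regime correlated ELISA mixture,
# Gaussian-spot slide images and fish-hook-like structures -- so every
# pipeline stage is testable without patient sera or downloads. Each
# generator returns a machine-readable `truth` record alongside the data.

#' Cohort specification for synthetic serum reactivity
#'
#' Defaults mirror the mapped study cohort: 93 sera, three enriched zones
#' at peptides 33-35, 46-52 and 62-67 with in-zone recognition probability
#' 0.7 over a 0.2 polyclonal background on a 79-peptide array.
#'
#' @param n_sera number of sera (default 93).
#' @param n_peptides number of array peptides (default 79).
#' @param zones list of `list(span = c(first, last), p = prob)` entries.
#' @param p_background recognition probability outside zones (default 0.2).
#' @param near_threshold optional `list(peptide =, p =)` planting a single
#'   just-below-cutoff peptide (e.g. `list(peptide = 14, p = 0.46)`).
#' @param n_zero number of fully non-reactive sera to force (default 0;
#'   the study observed 5 of 93).
#' @param groups optional per-serum group labels.
#' @param seed RNG seed.
#' @return object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_sera = 93L, n_peptides = 79L,
                        zones = list(list(span = c(33L, 35L), p = 0.7),
                                     list(span = c(46L, 52L), p = 0.7),
                                     list(span = c(62L, 67L), p = 0.7)),
                        p_background = 0.2, near_threshold = NULL,
                        n_zero = 0L, groups = NULL, seed = NULL) {
  probs <- c(p_background,
             vapply(zones, `[[`, numeric(1), "p"),
             if (!is.null(near_threshold)) near_threshold$p)
  if (any(probs < 0 | probs > 1)) pz_stop("bad_spec", "probabilities must be in [0,1]")
  for (z in zones) {
    if (z$span[1] < 1L || z$span[2] > n_peptides || z$span[1] > z$span[2]) {
      pz_stop("bad_spec", "zone span outside 1..n_peptides")
    }
  }
  if (n_zero < 0L || n_zero > n_sera) pz_stop("bad_spec", "bad n_zero")
  structure(list(n_sera = as.integer(n_sera), n_peptides = as.integer(n_peptides),
                 zones = zones, p_background = p_background,
                 near_threshold = near_threshold, n_zero = as.integer(n_zero),
                 groups = groups, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic reactivity matrix
#'
#' Independent Bernoulli calls per serum x peptide with zone-dependent
#' probabilities (the simplest model consistent with a polyclonal,
#' multi-zone response; within-serum clonal correlation is deliberately
#' not modelled). Optionally forces a chosen number of fully non-reactive
#' sera.
#'
#' @param spec a [cohort_spec()].
#' @return list with `matrix` (a [reactivity_matrix()]) and `truth`
#'   (per-peptide generating probabilities, planted zone table, ids of
#'   forced all-zero sera).
#' @export
gen_reactivity <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- rep(spec$p_background, spec$n_peptides)
  for (z in spec$zones) p[z$span[1]:z$span[2]] <- z$p
  if (!is.null(spec$near_threshold)) {
    p[spec$near_threshold$peptide] <- spec$near_threshold$p
  }
  pz_with_seed(spec$seed, {
    calls <- matrix(stats::rbinom(spec$n_sera * spec$n_peptides, 1L,
                                  rep(p, each = spec$n_sera)),
                    nrow = spec$n_sera, ncol = spec$n_peptides)
    zero_ids <- integer()
    if (spec$n_zero > 0L) {
      zero_ids <- sort(sample.int(spec$n_sera, spec$n_zero))
      calls[zero_ids, ] <- 0L
    }
    m <- reactivity_matrix(calls, group = spec$groups)
    truth <- list(
      prob = p,
      zones = data.frame(
        first_pep = vapply(spec$zones, function(z) z$span[1], integer(1)),
        last_pep = vapply(spec$zones, function(z) z$span[2], integer(1)),
        p = vapply(spec$zones, `[[`, numeric(1), "p")
      ),
      zero_sera = rownames(m)[zero_ids]
    )
    list(matrix = m, truth = truth)
  })
}

#' Specification for a two-regime ELISA mixture
#'
#' Emulates the two-pattern whole-molecule vs domain-4/5 scatter: a
#' correlated majority in which anti-D4/5 follows a noisy line in
#' anti-B2GP1, and an uncorrelated low-response minority. Whole-molecule
#' IgA anti-B2GP1 marginals are log-normal matched to the reported cohort
#' median (60.8 U) and IQR (40.1-121 U).
#'
#' @param n sera (default 93).
#' @param corr_frac fraction in the correlated regime (default 0.71).
#' @param target_r within-regime Pearson r for the correlated group
#'   (default 0.8).
#' @param meanlog,sdlog log-normal parameters of the anti-B2GP1 marginal.
#' @param intercept,slope line for the correlated regime's anti-D4/5.
#' @param uncorr_meanlog,uncorr_sdlog log-normal anti-D4/5 marginal of the
#'   uncorrelated (low-response) regime.
#' @param seed RNG seed.
#' @export
elisa_spec <- function(n = 93L, corr_frac = 0.71, target_r = 0.8,
                       meanlog = log(60.8), sdlog = 0.819,
                       intercept = 15, slope = 0.9,
                       uncorr_meanlog = log(12), uncorr_sdlog = 0.25,
                       seed = NULL) {
  if (corr_frac < 0 || corr_frac > 1) pz_stop("bad_spec", "corr_frac in [0,1]")
  if (target_r <= 0 || target_r >= 1) pz_stop("bad_spec", "need 0 < target_r < 1")
  structure(as.list(environment()), class = "elisa_spec")
}

#' Generate a synthetic two-regime ELISA panel
#'
#' In the correlated regime `anti_d4_5 = intercept + slope * anti_b2gp1 *
#' noise`, with multiplicative log-normal noise: antibody assay error
#' scales with the measured level, and the noise variance on the log scale
#' is solved in closed form so the regime's population Pearson correlation
#' (on the raw unit scale) equals `target_r` given the log-normal
#' anti-B2GP1 marginal. In the uncorrelated regime anti-D4/5 is drawn
#' independently from a low-level marginal. An independent anti-D1 column
#' with no built-in association is included.
#'
#' @param spec an [elisa_spec()].
#' @return list with `panel` (data.frame `id`, `anti_b2gp1_iga`,
#'   `anti_d4_5_iga`, `anti_d1_iga`) and `truth` (regime membership and
#'   generating parameters).
#' @export
gen_elisa <- function(spec = elisa_spec()) {
  stopifnot(inherits(spec, "elisa_spec"))
  pz_with_seed(spec$seed, {
    n <- spec$n
    n_corr <- round(spec$corr_frac * n)
    member <- sample(rep(c("correlated", "uncorrelated"), c(n_corr, n - n_corr)))
    x <- stats::rlnorm(n, spec$meanlog, spec$sdlog)
    # For X log-normal(m, s) and Y = b*X*exp(tau*W), corr(X, Y) =
    # sqrt((e^{s^2}-1)/(e^{s^2+tau^2}-1)); invert for tau at target_r.
    s2 <- spec$sdlog^2
    tau <- sqrt(log1p((exp(s2) - 1) / spec$target_r^2) - s2)
    y <- ifelse(member == "correlated",
                spec$intercept +
                  spec$slope * x * exp(stats::rnorm(n, 0, tau)),
                stats::rlnorm(n, spec$uncorr_meanlog, spec$uncorr_sdlog))
    d1 <- stats::rlnorm(n, log(14), 0.5)  # no built-in association
    panel <- data.frame(id = sprintf("S%03d", seq_len(n)),
                        anti_b2gp1_iga = x,
                        anti_d4_5_iga = pmax(0, y),
                        anti_d1_iga = d1)
    list(panel = panel,
         truth = list(member = member, tau = tau, spec = spec))
  })
}

#' Standard slide layout on a regular grid
#'
#' 79 peptide spots followed by `n_neg` negative (buffer-only) spots laid
#' out row-major on a regular grid.
#'
#' @param n_peptides peptide spots (default 79).
#' @param n_neg negative spots (default 5).
#' @param n_cols grid columns (default 12).
#' @param spacing center-to-center pixel spacing (default 22).
#' @param radius fixed-circle radius in pixels (default 6).
#' @param margin pixels from image edge to first spot center (default 22).
#' @return an [array_layout()] plus attributes `image_nrow`, `image_ncol`.
#' @export
standard_layout <- function(n_peptides = 79L, n_neg = 5L, n_cols = 12L,
                            spacing = 22L, radius = 6L, margin = 22L) {
  n <- n_peptides + n_neg
  n_rows <- ceiling(n / n_cols)
  idx <- seq_len(n) - 1L
  spots <- data.frame(
    spot_id = c(sprintf("P%02d", seq_len(n_peptides)),
                sprintf("NEG%d", seq_len(n_neg))),
    role = rep(c("peptide", "negative"), c(n_peptides, n_neg)),
    peptide = c(seq_len(n_peptides), rep(NA_integer_, n_neg)),
    row = margin + (idx %/% n_cols) * spacing,
    col = margin + (idx %% n_cols) * spacing,
    radius = radius
  )
  layout <- array_layout(spots, require_standard = (n_peptides == 79L && n_neg >= 5L))
  attr(layout, "image_nrow") <- margin * 2L + (n_rows - 1L) * spacing
  attr(layout, "image_ncol") <- margin * 2L + (n_cols - 1L) * spacing
  layout
}

#' Slide specification for synthetic array images
#'
#' @param layout an [array_layout()]; default [standard_layout()].
#' @param bg_mean,bg_sd background pixel intensity mean and SD (16-bit
#'   scale).
#' @param amplitude peak added intensity of a bound peptide's spot.
#' @param unbound_amplitude peak intensity of unbound peptide and negative
#'   spots (default 0).
#' @param psf_sigma Gaussian spot width in pixels.
#' @param seed RNG seed.
#' @export
slide_spec <- function(layout = standard_layout(), bg_mean = 800, bg_sd = 60,
                       amplitude = 20000, unbound_amplitude = 0,
                       psf_sigma = 2.5, seed = NULL) {
  if (bg_mean < 0 || bg_sd < 0 || amplitude < 0 || unbound_amplitude < 0) {
    pz_stop("bad_spec", "intensities must be non-negative")
  }
  structure(as.list(environment()), class = "slide_spec")
}

#' Generate a synthetic slide image
#'
#' Gaussian spots at the layout centers (amplitude per bound status) on a
#' Gaussian background, rounded and clipped to the 16-bit range.
#'
#' @param spec a [slide_spec()].
#' @param bound_peptides integer set of peptide indices carrying signal.
#' @return list with `image` (integer matrix), `layout`, and `truth`
#'   (bound set and spec).
#' @export
gen_slide <- function(spec = slide_spec(), bound_peptides = integer()) {
  stopifnot(inherits(spec, "slide_spec"))
  layout <- spec$layout
  nr <- attr(layout, "image_nrow")
  nc <- attr(layout, "image_ncol")
  if (is.null(nr) || is.null(nc)) {
    nr <- ceiling(max(layout$row + layout$radius) + layout$radius[1])
    nc <- ceiling(max(layout$col + layout$radius) + layout$radius[1])
  }
  if (any(layout$row + layout$radius > nr | layout$col + layout$radius > nc)) {
    pz_stop("layout_overflow", "layout does not fit the image")
  }
  pz_with_seed(spec$seed, {
    img <- matrix(stats::rnorm(nr * nc, spec$bg_mean, spec$bg_sd), nr, nc)
    rows <- seq_len(nr)
    cols <- seq_len(nc)
    for (i in seq_len(nrow(layout))) {
      amp <- if (layout$role[i] == "peptide" && layout$peptide[i] %in% bound_peptides)
        spec$amplitude else spec$unbound_amplitude
      if (amp <= 0) next
      g <- amp * outer(exp(-(rows - layout$row[i])^2 / (2 * spec$psf_sigma^2)),
                       exp(-(cols - layout$col[i])^2 / (2 * spec$psf_sigma^2)))
      img <- img + g
    }
    img <- pmin(pmax(round(img), 0), 65535)
    storage.mode(img) <- "integer"
    list(image = img, layout = layout,
         truth = list(bound_peptides = sort(as.integer(bound_peptides)), spec = spec))
  })
}

#' Write a synthetic slide as a 16-bit grayscale TIFF
#'
#' The full 16-bit intensity range survives a write/read round trip
#' through [read_array_image()].
#'
#' @param slide result of [gen_slide()].
#' @param path output `.tif` path.
#' @export
write_slide_tiff <- function(slide, path) {
  tiff::writeTIFF(slide$image / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Generate a synthetic structure with known face sidedness
#'
#' Builds an alpha-carbon trace whose base lies in a reference plane, with
#' chosen residue spans displaced to the positive ("L") or negative ("J")
#' side, so every residue has a generator-known face label under the
#' signed-distance rule.
#'
#' Shapes: `"fishhook"` (an L-shaped polyline in the plane, like the open
#' conformation viewed side-on), `"plane"` (scattered points) and
#' `"helix"` (a flattened helical wave).
#'
#' @param n_res number of residues (default 326).
#' @param shape `"fishhook"`, `"plane"` or `"helix"`.
#' @param l_spans list of `c(first, last)` residue spans displaced to the
#'   L side.
#' @param j_spans spans displaced to the J side.
#' @param offset displacement in Angstrom (default 5).
#' @param base_sd out-of-plane jitter SD for base residues (default 0.3).
#' @param edge_delta band half-width used for the truth labels
#'   (default 1.5, matching [fit_face_plane()]).
#' @param seed RNG seed.
#' @return list with `model` (a `structure_model`) and `truth` (per-residue
#'   labels under the generator's own signed-distance rule, plus the spans).
#' @export
gen_structure <- function(n_res = 326L, shape = c("fishhook", "plane", "helix"),
                          l_spans = list(), j_spans = list(), offset = 5,
                          base_sd = 0.3, edge_delta = 1.5, seed = NULL) {
  shape <- match.arg(shape)
  for (sp in c(l_spans, j_spans)) {
    if (sp[1] < 1L || sp[2] > n_res || sp[1] > sp[2]) {
      pz_stop("bad_spec", "span outside 1..n_res")
    }
  }
  pz_with_seed(seed, {
    t <- seq_len(n_res)
    base <- switch(shape,
      fishhook = {
        # long arm then a quarter-turn into the short arm, all in the xy plane
        n_long <- round(0.7 * n_res)
        xx <- c(seq(0, by = 3.8, length.out = n_long),
                rep(3.8 * (n_long - 1), n_res - n_long))
        yy <- c(rep(0, n_long), seq(3.8, by = 3.8, length.out = n_res - n_long))
        cbind(x = xx + stats::rnorm(n_res, 0, 0.5),
              y = yy + stats::rnorm(n_res, 0, 0.5))
      },
      plane = cbind(x = stats::runif(n_res, 0, 100),
                    y = stats::runif(n_res, 0, 100)),
      helix = cbind(x = t * 1.5, y = 25 * sin(t / 4))
    )
    z <- stats::rnorm(n_res, 0, base_sd)
    for (sp in l_spans) z[sp[1]:sp[2]] <- offset + stats::rnorm(sp[2] - sp[1] + 1, 0, base_sd)
    for (sp in j_spans) z[sp[1]:sp[2]] <- -offset + stats::rnorm(sp[2] - sp[1] + 1, 0, base_sd)
    model <- data.frame(resno = t, x = base[, "x"], y = base[, "y"], z = z)
    attr(model, "chain") <- "A"
    attr(model, "unresolved") <- integer()
    class(model) <- c("structure_model", class(model))
    zc <- z - mean(z)
    truth_lab <- ifelse(zc > edge_delta, "L", ifelse(zc < -edge_delta, "J", "edge"))
    list(model = model,
         truth = list(labels = stats::setNames(truth_lab, t),
                      l_spans = l_spans, j_spans = j_spans,
                      offset = offset, edge_delta = edge_delta))
  })
}

#' Monte-Carlo specificity of the positivity threshold under a Gaussian null
#'
#' Simulates slides on which every spot IOD (peptide and negative alike) is
#' drawn i.i.d. from one Gaussian, applies the background-plus-kSD
#' threshold per slide, and returns the mean fraction of peptide spots
#' correctly left uncalled. Ties the threshold's construction to its
#' claimed >95% confidence that a called signal is real.
#'
#' @param n_slides number of simulated slides (default 10000).
#' @param n_peptides,n_neg spots per slide (defaults 79 and 5).
#' @param n_random peptides sampled for the SD term (default 15).
#' @param k SD multiplier (default 2).
#' @param mean,sd the null IOD distribution (defaults 1000, 100; the
#'   specificity is location/scale-free under the rule).
#' @param seed RNG seed.
#' @return mean specificity as a fraction in `[0,1]`, with attribute
#'   `per_slide` (per-slide specificities).
#' @export
simulate_null_specificity <- function(n_slides = 10000L, n_peptides = 79L,
                                      n_neg = 5L, n_random = 15L, k = 2,
                                      mean = 1000, sd = 100, seed = NULL) {
  pz_with_seed(seed, {
    negs <- matrix(stats::rnorm(n_slides * n_neg, mean, sd), n_slides, n_neg)
    peps <- matrix(stats::rnorm(n_slides * n_peptides, mean, sd), n_slides, n_peptides)
    neg_mean <- rowMeans(negs)
    rand_sd <- vapply(seq_len(n_slides), function(i) {
      stats::sd(peps[i, sample.int(n_peptides, n_random)])
    }, numeric(1))
    thr <- neg_mean + k * rand_sd
    spec_per_slide <- rowMeans(peps <= thr)
    structure(mean(spec_per_slide), per_slide = spec_per_slide)
  })
}
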