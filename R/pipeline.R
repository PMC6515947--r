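# End-to-end pipeline driver: design -> quantify -> map-epitopes ->
# serology -> structure-map, with per-stage error context, TSV outputs and
# a seed-recording run log. All outputs are deterministic given the config
# (no timestamps), so a rerun with identical config and seeds reproduces
# byte-identical files.

default_run_config <- function() {
  list(
    peptide_table = NULL,      # NULL -> packaged 79-peptide design
    out_dir = "pepzone_run",
    reactivity = NULL,         # reactivity TSV (one row per serum)
    slides = NULL,             # list of list(image=, layout=, serum_id=)
    elisa = NULL,              # ELISA panel TSV
    pdb = NULL,                # PDB path
    chain = NULL,
    anchors = 39:43,
    edge_delta = 1.5,
    threshold = list(n_random = 15L, k = 2, seed = 1L),
    antigenicity_threshold = 0.5,
    near_threshold_low = 0.45,
    cutoffs = NULL             # named list overriding cutoff_set()
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("stage %s: %s", stage, conditionMessage(e)),
      stage = stage,
      class = c("pepzone_stage_error", class(e)[class(e) != "condition"])
    ))
  })
}

#' Run the full epitope-mapping pipeline
#'
#' Executes the configured stages and writes all intermediate and summary
#' tables under `out_dir`:
#' \describe{
#'   \item{design}{reconstruct the antigen from the peptide table, re-tile
#'     and annotate domains; writes `antigen.fasta`, `tiling.tsv`.}
#'   \item{quantify}{fixed-circle IOD + threshold calls per slide (one
#'     serum per slide); writes `quants_<serum>.tsv` and assembles
#'     `reactivity.tsv`. Skipped when a ready-made reactivity TSV is
#'     supplied.}
#'   \item{map-epitopes}{antigenicity profile, high-antigenicity zones,
#'     near-threshold report, per-serum breadth; writes `profile.tsv`,
#'     `zones.tsv`, `breadth.tsv`.}
#'   \item{serology}{positivity classification, whole-molecule vs domain
#'     correlations and the heuristic two-regime split; writes
#'     `serology.tsv`, `correlations.tsv`.}
#'   \item{structure-map}{face plane, residue labels and zone face
#'     composition; writes `face_labels.tsv`, `zone_faces.tsv`.}
#' }
#' A `run_log.txt` records package version, config hash and seeds. Stage
#' errors are rethrown with the failing stage named.
#'
#' @param config list (see `default` entries in the source) or path to a
#'   YAML file with the same keys.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  results <- list(config = cfg)

  # -- design ---------------------------------------------------------------
  design <- run_stage("design", {
    path <- cfg$peptide_table %||% pepzone_extdata("peptide_table.tsv")
    peps <- read_peptide_table(path)
    antigen <- stitch_peptides(peps)
    tiled <- annotate_domains(tile_protein(antigen))
    write_antigen_fasta(antigen, out("antigen.fasta"))
    write_tiling_tsv(tiled, out("tiling.tsv"))
    list(peptides = peps, antigen = antigen, tiled = tiled)
  })
  results$design <- design

  # -- quantify -------------------------------------------------------------
  m <- NULL
  if (!is.null(cfg$reactivity)) {
    m <- run_stage("quantify", read_reactivity_tsv(cfg$reactivity))
  } else if (!is.null(cfg$slides)) {
    m <- run_stage("quantify", {
      rows <- lapply(seq_along(cfg$slides), function(i) {
        sl <- cfg$slides[[i]]
        for (f in c("image", "layout")) {
          if (is.character(sl[[f]]) && !file.exists(sl[[f]])) {
            pz_stop("missing_file", sprintf("%s file '%s' not found", f, sl[[f]]))
          }
        }
        img <- if (is.character(sl$image)) read_array_image(sl$image) else sl$image
        lay <- if (is.character(sl$layout)) read_layout_tsv(sl$layout) else sl$layout
        q <- measure_iod(img, lay)
        thr <- compute_threshold(q, n_random = cfg$threshold$n_random,
                                 k = cfg$threshold$k, seed = cfg$threshold$seed)
        sid <- sl$serum_id %||% sprintf("S%03d", i)
        write_quants_tsv(q, out(sprintf("quants_%s.tsv", sid)), model = thr)
        as.integer(call_positive(q, thr))
      })
      calls <- do.call(rbind, rows)
      rownames(calls) <- vapply(seq_along(cfg$slides), function(i) {
        cfg$slides[[i]]$serum_id %||% sprintf("S%03d", i)
      }, character(1))
      reactivity_matrix(calls)
    })
  }
  if (!is.null(m)) {
    write_reactivity_tsv(m, out("reactivity.tsv"))
    results$reactivity <- m

    # -- map-epitopes -------------------------------------------------------
    results$epitopes <- run_stage("map-epitopes", {
      profile <- recognition_frequency(m)
      zones <- detect_zones(profile, threshold = cfg$antigenicity_threshold,
                            peptides = design$tiled)
      near <- near_threshold_report(profile, low = cfg$near_threshold_low,
                                    threshold = cfg$antigenicity_threshold)
      breadth <- serum_breadth(m)
      pz_write_tsv(data.frame(peptide = seq_along(profile),
                              fraction = as.numeric(profile)),
                   out("profile.tsv"), config = cfg$antigenicity_threshold)
      pz_write_tsv(zones, out("zones.tsv"), config = cfg$antigenicity_threshold)
      pz_write_tsv(data.frame(serum_id = names(breadth$per_serum),
                              n_recognized = as.integer(breadth$per_serum)),
                   out("breadth.tsv"))
      list(profile = profile, zones = zones, near_threshold = near,
           breadth = breadth)
    })
  }

  # -- serology -------------------------------------------------------------
  if (!is.null(cfg$elisa)) {
    results$serology <- run_stage("serology", {
      panel <- if (is.character(cfg$elisa)) read_elisa_tsv(cfg$elisa) else cfg$elisa
      cuts <- do.call(cutoff_set, as.list(cfg$cutoffs %||% list()))
      flags <- classify_positivity(panel, cuts)
      pz_write_tsv(flags, out("serology.tsv"), config = as.list(cuts))
      cors <- list()
      if (all(c("anti_b2gp1_iga", "anti_d4_5_iga") %in% names(panel))) {
        cors$d4_5 <- pearson_ci(panel$anti_b2gp1_iga, panel$anti_d4_5_iga)
        cors$d4_5_split <- split_correlation(panel$anti_b2gp1_iga,
                                             panel$anti_d4_5_iga)
      }
      if (all(c("anti_b2gp1_iga", "anti_d1_iga") %in% names(panel))) {
        cors$d1 <- pearson_ci(panel$anti_b2gp1_iga, panel$anti_d1_iga)
      }
      ctab <- do.call(rbind, lapply(names(cors), function(nm) {
        cr <- cors[[nm]]
        if (inherits(cr, "correlation_result")) {
          data.frame(comparison = nm, r = cr$r, ci_lo = cr$ci[1],
                     ci_hi = cr$ci[2], p = cr$p, n = cr$n)
        } else {
          data.frame(comparison = c(paste0(nm, "_A"), paste0(nm, "_B")),
                     r = c(cr$r_A$r, cr$r_B$r),
                     ci_lo = c(cr$r_A$ci[1], cr$r_B$ci[1]),
                     ci_hi = c(cr$r_A$ci[2], cr$r_B$ci[2]),
                     p = c(cr$r_A$p, cr$r_B$p),
                     n = c(cr$r_A$n, cr$r_B$n))
        }
      }))
      if (!is.null(ctab)) pz_write_tsv(ctab, out("correlations.tsv"))
      list(positivity = flags, correlations = cors)
    })
  }

  # -- structure-map --------------------------------------------------------
  if (!is.null(cfg$pdb)) {
    results$structure <- run_stage("structure-map", {
      model <- read_structure(cfg$pdb, chain = cfg$chain)
      plane <- fit_face_plane(model, anchors = cfg$anchors,
                              edge_delta = cfg$edge_delta)
      labels <- classify_faces(model, plane)
      pz_write_tsv(data.frame(resno = as.integer(names(labels)), face = labels),
                   out("face_labels.tsv"))
      faces <- NULL
      if (!is.null(results$epitopes) && nrow(results$epitopes$zones)) {
        faces <- zone_face_fraction(results$epitopes$zones, labels)
        pz_write_tsv(faces, out("zone_faces.tsv"))
      }
      list(model = model, plane = plane, labels = labels, zone_faces = faces)
    })
  }

  writeLines(c(
    sprintf("pepzone %s", as.character(utils::packageVersion("pepzone"))),
    sprintf("config_hash: %s", pz_config_hash(cfg)),
    sprintf("threshold_seed: %s", cfg$threshold$seed),
    sprintf("stages: %s", paste(setdiff(names(results), "config"), collapse = ", "))
  ), out("run_log.txt"))

  invisible(results)
}
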