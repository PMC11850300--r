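#' Run the full triad pipeline from a single configuration
#'
#' One entry point wiring the stages together: (optionally) generate
#' synthetic inputs, filter contacts by RNA--DNA peaks, extend the protein
#' peak sets, build triads, run the permutation null per protein, and emit
#' the downstream statistics. Every output file is written under
#' `out_dir` and recorded, together with parameters, seeds and per-stage
#' row counts, in a JSON manifest. A fixed seed makes the run idempotent.
#'
#' @param config A named list, or the path to a YAML file with the same
#'   structure. Recognised fields: `out_dir` (required); either `synth`
#'   (a list of [synth_config()] arguments) or input paths `contacts`,
#'   `rd_peaks`, `pd_peaks`, `pr_peaks`, `genome`, `compartments`,
#'   `states`; parameters `pd_ext` (2000), `pr_ext` (100), `min_overlap`
#'   (19), `ratio_related` (0.8), `n_reps` (0 = skip simulation),
#'   `sim_proteins` (default: all), `seed` (1).
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(pd_ext = 2000, pr_ext = 100, min_overlap = 19,
         ratio_related = 0.8, n_reps = 0, sim_proteins = NULL, seed = 1L),
    config)
  stopifnot(cfg$pd_ext >= 0, cfg$pr_ext >= 0, cfg$min_overlap >= 1,
            cfg$ratio_related > 0, cfg$ratio_related <= 1)
  if (is.null(cfg$out_dir)) abort("config must name an `out_dir`.")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  emit <- function(x, name, writer = readr::write_tsv) {
    path <- file.path(cfg$out_dir, name)
    writer(x, path)
    outputs[[name]] <<- path
    path
  }

  if (!is.null(cfg$synth)) {
    syn <- synth_generate(do.call(synth_config, cfg$synth))
    gen <- syn$genome; compartments <- syn$compartments
    states <- syn$states; contacts <- syn$contacts
    rd_peaks <- syn$rd_peaks; pd_peaks <- syn$pd_peaks
    pr_peaks <- syn$pr_peaks
    emit(syn$truth, "truth.tsv")
  } else {
    need <- c("contacts", "rd_peaks", "pd_peaks", "pr_peaks", "genome")
    for (f in need) {
      if (is.null(cfg[[f]])) abort(paste0("config lacks input `", f, "`."))
      if (!file.exists(cfg[[f]])) abort(paste0("missing input file: ", cfg[[f]]))
    }
    gen <- read_chrom_sizes(cfg$genome)
    contacts <- read_contacts(cfg$contacts)
    rd_peaks <- read_peaks_bed(cfg$rd_peaks, kind = "RD")
    pd_peaks <- read_peaks_bed(cfg$pd_peaks, kind = "PD")
    pr_tab <- readr::read_tsv(cfg$pr_peaks, col_types = readr::cols(),
                              progress = FALSE)
    pr_peaks <- as_tibble(pr_tab) # TSV with owner/rna_id/biotype columns
    compartments <- if (!is.null(cfg$compartments)) {
      read_labeled_track(cfg$compartments)
    } else NULL
    states <- if (!is.null(cfg$states)) read_labeled_track(cfg$states) else NULL
  }

  filtered <- filter_rd_by_peaks(contacts, rd_peaks)
  pd_ext <- extend_pd_peaks(pd_peaks, gen, cfg$pd_ext)
  pr_ext <- extend_pr_peaks(pr_peaks, gen, cfg$pr_ext)
  triads <- build_triads(filtered, pd_ext, pr_ext, cfg$min_overlap)
  emit(triads, "triads.tsv", write_triads)

  sim_tab <- NULL
  if (cfg$n_reps > 0 && nrow(triads) > 0 && !is.null(compartments)) {
    prots <- cfg$sim_proteins %||%
      intersect(unique(pd_ext$owner), unique(pr_ext$owner))
    relmap <- protein_distance_matrix(pr_ext)
    sim_tab <- purrr::imap(prots, function(p, i) {
      glance(simulate_null(p, filtered, pd_ext, pr_ext, compartments, gen,
                           relmap = relmap, n_reps = cfg$n_reps,
                           min_overlap = cfg$min_overlap,
                           ratio_related = cfg$ratio_related,
                           seed = cfg$seed + i))
    }) |> list_rbind()
    emit(sim_tab, "simulation.tsv")
  }

  stats_files <- list()
  ct <- tryCatch(cis_trans_shift_test(filtered, triads), error = function(e) NULL)
  if (!is.null(ct)) {
    emit(glance(ct), "cis_trans_test.tsv")
  }
  if (!is.null(states) && nrow(triads) > 0) {
    sd_tab <- purrr::map(unique(triads$protein), function(p) {
      d <- state_distribution(triads[triads$protein == p, ], states, gen,
                              weight = "count")
      d$protein <- p
      as_tibble(d)
    }) |> list_rbind()
    emit(sd_tab, "state_distribution.tsv")
  }
  if (!is.null(compartments) && nrow(triads) > 0) {
    emit(compartment_density(triads, compartments, gen),
         "compartment_density.tsv")
  }

  manifest <- list(
    params = cfg[c("pd_ext", "pr_ext", "min_overlap", "ratio_related",
                   "n_reps", "seed")],
    counts = list(
      contacts = nrow(contacts), filtered_contacts = nrow(filtered),
      pd_peaks = nrow(pd_peaks), pr_peaks = nrow(pr_peaks),
      triads = nrow(triads),
      sim_reps = if (is.null(sim_tab)) 0 else cfg$n_reps
    ),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
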