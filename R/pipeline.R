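#' Run the full population-structure pipeline
#'
#' Orchestrates every stage end-to-end on either a simulated dataset or
#' PLINK/VCF input: MAF filtering, IBS relationship matrix, PCA,
#' pairwise F_ST (with NEXUS export), supervised and unsupervised
#' admixture, parallel analysis plus contribution scores, the k-NN
#' population network, ROH detection with summaries and length
#' classes, ROH islands, and the pedigree comparison.  Each stage
#' writes TSV/GraphML/NEXUS artifacts into `out_dir` and a
#' `manifest.json` records parameters, seeds, and output hashes.
#' Stage randomness is driven by per-stage seeds derived
#' deterministically from the master seed, so identical configs
#' reproduce identical outputs.
#'
#' @param config Named list (or path to a YAML file) with optional
#'   entries: `sim` (arguments for [sim_config()]), or `ped_path` /
#'   `map_path` / `vcf_path` for real input; `stages` (named logical
#'   toggles: relationship, admixture, contributors, network, roh,
#'   islands, pedigree); `maf_threshold` (default 0.05), `knn_k`
#'   (default 10), `unsupervised_K` (default number of populations),
#'   `l_auto_mb` (default: simulated autosome length, else 2280.92),
#'   `roh` (arguments for [roh_params()]), `home_breed`,
#'   `pa_iterations` (default 200), `seed` (default 1).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- as.integer(config$seed %||% 1L)
  set.seed(seed)
  stage_seed <- stats::setNames(sample.int(.Machine$integer.max - 1L, 8L),
                                c("sim", "relationship", "admixture",
                                  "contributors", "network", "roh", "islands",
                                  "pedigree"))
  stages_on <- function(name) {
    s <- config$stages
    is.null(s[[name]]) || isTRUE(s[[name]])
  }
  artifacts <- character(0)
  keep <- function(path) { artifacts <<- c(artifacts, path); path }
  tsv <- function(df, name, row_names = FALSE) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = row_names, col.names = NA_row(row_names))
    keep(path)
  }
  NA_row <- function(rn) if (rn) NA else TRUE

  # ---- input stage -------------------------------------------------
  ped <- NULL; truth <- NULL
  if (!is.null(config$vcf_path)) {
    say("loading VCF %s", config$vcf_path)
    dataset <- read_vcf(config$vcf_path)
  } else if (!is.null(config$ped_path)) {
    say("loading PLINK text %s", config$ped_path)
    dataset <- read_plink_text(config$ped_path, config$map_path)
  } else {
    sim_args <- config$sim %||% list()
    sim_args$seed <- sim_args$seed %||% stage_seed[["sim"]]
    cfg <- do.call(sim_config, sim_args)
    say("simulating %d breeds x %d founders, %d SNPs", cfg$n_breeds,
        cfg$n_founders_per_breed, cfg$m_snps)
    sim <- simulate_breeds(cfg)
    dataset <- sim$dataset
    ped <- sim$pedigree
    truth <- sim$truth
    write_plink_text(dataset, keep(file.path(out_dir, "genotypes.ped")),
                     keep(file.path(out_dir, "genotypes.map")))
    write_sim_truth(truth, keep(file.path(out_dir, "truth.tsv")))
    if (is.null(config$l_auto_mb)) {
      config$l_auto_mb <- sum(cfg$chromosomes$length_bp) / 1e6
    }
  }
  l_auto <- config$l_auto_mb %||% 2280.92

  say("MAF filter at %.3g", config$maf_threshold %||% 0.05)
  filtered <- maf_filter(dataset, config$maf_threshold %||% 0.05)

  G <- D <- NULL
  if (stages_on("relationship")) {
    say("relationship stage")
    G <- ibs_matrix(filtered)
    D <- distance_matrix(G)
    tsv(as.data.frame(G), "ibs_matrix.tsv", row_names = TRUE)
    pca <- pca_grm(G)
    tsv(data.frame(id = rownames(pca$scores), pca$scores[, 1:min(10, ncol(pca$scores))],
                   stringsAsFactors = FALSE), "pca_scores.tsv")
    if (length(unique(filtered$populations)) >= 2) {
      fst <- pairwise_fst(filtered)
      tsv(as.data.frame(fst), "fst_matrix.tsv", row_names = TRUE)
      export_nexus_distances(fst, keep(file.path(out_dir, "fst_distances.nex")))
    }
  }

  fit_sup <- NULL
  if (stages_on("admixture")) {
    pops <- sort(unique(filtered$populations))
    refs <- setdiff(pops, "admixed")
    targets <- filtered$ids[filtered$populations == "admixed"]
    if (length(targets) && length(refs) >= 1) {
      say("supervised admixture, K = %d, %d targets", length(refs), length(targets))
      fit_sup <- admix_supervised(filtered, refs, targets)
      tsv(data.frame(id = rownames(fit_sup$Q), fit_sup$Q, stringsAsFactors = FALSE),
          "admixture_supervised_Q.tsv")
      if (!is.null(config$home_breed) && config$home_breed %in% colnames(fit_sup$Q)) {
        tsv(data.frame(id = rownames(fit_sup$Q),
                       a_gen = agen(fit_sup, config$home_breed)), "agen.tsv")
      }
    }
    K <- config$unsupervised_K %||% max(2L, length(refs))
    say("unsupervised admixture, K = %d", K)
    fit_un <- admix_unsupervised(filtered, K, seed = stage_seed[["admixture"]])
    tsv(data.frame(id = rownames(fit_un$Q), fit_un$Q, stringsAsFactors = FALSE),
        "admixture_unsupervised_Q.tsv")
  }

  scores <- NULL
  if (stages_on("contributors") && !is.null(G)) {
    say("contributor scores")
    pa <- parallel_analysis(G, filtered, P = 0.01,
                            iterations = config$pa_iterations %||% 200,
                            seed = stage_seed[["contributors"]])
    scores <- contribution_scores(G, max(1L, pa$k_significant))
    tsv(scores, "contribution_scores.tsv")
  }

  roh_summary <- NULL
  segments <- NULL
  if (stages_on("roh")) {
    say("ROH detection")
    rp <- do.call(roh_params, config$roh %||% list())
    segments <- detect_roh(dataset, rp)
    tsv(segments, "roh_segments.tsv")
    roh_summary <- summarize_roh(segments, dataset, l_auto)
    tsv(roh_summary$individuals, "roh_individuals.tsv")
    tsv(roh_summary$populations, "roh_populations.tsv")
    if (nrow(segments)) {
      pops_vec <- stats::setNames(dataset$populations, dataset$ids)
      tsv(roh_length_classes(segments, pops_vec), "roh_length_classes.tsv")
    }
  }

  if (stages_on("islands") && !is.null(segments)) {
    say("ROH islands")
    isl <- islands_by_population(segments, dataset)
    cls <- classify_islands(isl, dataset)
    tsv(do.call(rbind, cls$islands), "roh_islands.tsv")
    tsv(cls$overlaps, "roh_island_overlaps.tsv")
    tsv(cls$summary, "roh_island_summary.tsv")
  }

  if (stages_on("network") && !is.null(D)) {
    say("k-NN network")
    net <- knn_network(D, k = min(config$knn_k %||% 10, nrow(D) - 1))
    # extend the supervised Q to reference individuals (unit ancestry in
    # their own panel) so every network node carries admixture attributes
    Q_full <- NULL
    if (!is.null(fit_sup)) {
      Q_full <- matrix(0, nrow(D), ncol(fit_sup$Q),
                       dimnames = list(rownames(D), colnames(fit_sup$Q)))
      hit <- match(rownames(fit_sup$Q), rownames(D))
      Q_full[hit[!is.na(hit)], ] <- fit_sup$Q[!is.na(hit), ]
      refs_in <- setdiff(rownames(D), rownames(fit_sup$Q))
      pop_of <- stats::setNames(filtered$populations, filtered$ids)
      for (id in refs_in) {
        if (pop_of[[id]] %in% colnames(Q_full)) Q_full[id, pop_of[[id]]] <- 1
      }
    }
    net <- annotate_network(net,
                            scores = scores,
                            roh_summary = if (!is.null(roh_summary)) {
                              ri <- roh_summary$individuals
                              ri[match(rownames(D), ri$id), ]
                            },
                            admixture = Q_full,
                            populations = stats::setNames(filtered$populations,
                                                          filtered$ids))
    write_network_graphml(net, keep(file.path(out_dir, "network.graphml")))
    tsv(edge_weight_style(net), "network_edges.tsv")
  }

  if (stages_on("pedigree") && !is.null(ped)) {
    say("pedigree stage")
    fped <- pedigree_inbreeding(ped)
    tsv(data.frame(id = names(fped), f_ped = fped), "fped.tsv")
    home <- config$home_breed %||% ped$breed[!is.na(ped$breed)][1]
    aped <- pedigree_admixture(ped, home_breed = home,
                               purebred_cutoff_year = config$purebred_cutoff_year %||% 1950)
    tsv(data.frame(id = names(aped), a_ped = aped), "aped.tsv")
    if (!is.null(roh_summary)) {
      froh <- stats::setNames(roh_summary$individuals$f_roh / 100,
                              roh_summary$individuals$id)
      cmp <- compare_genomic_pedigree(froh = froh, fped = fped)
      tsv(as.data.frame(cmp), "pedigree_comparison.tsv")
    }
  }

  manifest <- list(seed = seed, stage_seeds = as.list(stage_seed),
                   config = config[setdiff(names(config), "stages")],
                   stages = config$stages %||% "all",
                   n_individuals = length(dataset$ids),
                   n_markers_raw = nrow(dataset$map),
                   n_markers_filtered = nrow(filtered$map),
                   package_version = as.character(utils::packageVersion("herdstruct")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   artifacts = as.list(tools::md5sum(sort(artifacts))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dataset = dataset, filtered = filtered, G = G,
                 segments = segments, roh_summary = roh_summary,
                 manifest = manifest, out_dir = out_dir))
}
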