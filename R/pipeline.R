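#' Default pipeline configuration
#'
#' Every analysis parameter with a field-standard printed value defaults to
#' it: 150 bp overlap center distance (300 bp null window), 150 bp ATAC
#' extension, 1 kb hotspot window, +/-500 kb regulatory domains (GREAT
#' basal 5 kb up / 1 kb down, 500 kb extension), differential thresholds
#' fold > 3 / TPM > 5 / alpha 0.05, population-set thresholds TPM > 10 /
#' fold > 2. Remaining knobs parameterize the simulated inputs.
#'
#' @param seed master seed; all stage seeds are derived from it.
#' @param ... overrides for any default field.
#' @return list of class `run_config`.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    # simulation
    n_chroms = 1, chrom_len = 2e6, n_genes = 200,
    factors = c("Six2", "Hoxd11", "Osr1", "Wt1"),
    n_anchors = 60, n_specific = 80, jitter_sd = 50,
    width_range = c(150, 400), cobinding_prob = 0.9,
    accessible_fraction = 0.25, region_width = 2000,
    motif_consensus = "TCAAGTTTCA", plant_prob = 0.5, plant_sd = 20,
    populations = c("progenitor", "self_renewing", "differentiating"),
    n_planted_genes = 30, planted_fold = 8, replicates = 3,
    dispersion = 0.3,
    # analysis
    max_center_dist = 150, atac_extend = 150, hotspot_window = 1000,
    min_factors = NULL, domain_mode = "flank_500kb", flank = 5e5,
    basal_up = 5000, basal_down = 1000, extension = 5e5,
    n_random = 10, n_matched_sets = 5, motif_window = 150,
    scan_window = 300, motif_pvalue = 2e-4,
    de_fold = 3, de_min_tpm = 5, de_alpha = 0.05,
    set_min_tpm = 10, set_fold = 2,
    contact_max_range = Inf)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Load a configuration file (JSON or YAML)
#'
#' Fields override [default_config()] defaults; unknown fields are an
#' error. YAML requires the optional `yaml` package.
#'
#' @param path `.json` or `.yaml`/`.yml` file.
#' @return `run_config`.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(default_config, c(list(seed = if (is.null(vals$seed)) 1
                                        else vals$seed),
                            vals[setdiff(names(vals), "seed")]))
}

write_table_with_params <- function(df, path, params) {
  hdr <- sprintf("# %s", jsonlite::toJSON(params, auto_unbox = TRUE,
                                          digits = NA))
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' Run the full simulated analysis end to end
#'
#' simulate genome / accessible chromatin / co-bound peaks / planted
#' motifs / expression, then: pairwise overlap significance table,
#' hotspot calling, motif enrichment against matched random sets,
#' regulatory-domain target assignment, category enrichment of the
#' expression-derived gene sets, category fractions for per-combination
#' unique targets, and the bundled toy-locus rearrangement contact
#' predictions. Every table is written as TSV with the exact parameters
#' embedded in a `#` header line; re-running with the same config gives
#' byte-identical outputs.
#'
#' @param config `run_config` (see [default_config()]).
#' @param out_dir output directory (created; must be empty or absent).
#' @return invisibly, a list of the in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pj <- function(...) file.path(out_dir, ...)
  params_all <- unclass(config)
  jsonlite::write_json(params_all, pj("params.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  ## ---- simulate ----
  sim <- simulate_genome(config$n_chroms, config$chrom_len, config$n_genes,
                         seed = derive_seed(config$seed, "genome"))
  spec <- cobinding_spec(config$factors, n_anchors = config$n_anchors,
                         n_specific = config$n_specific,
                         jitter_sd = config$jitter_sd,
                         width_range = config$width_range,
                         cobinding_matrix = config$cobinding_prob,
                         accessible_fraction = config$accessible_fraction,
                         region_width = config$region_width)
  pk <- simulate_peaks(spec, sim$genome,
                       seed = derive_seed(config$seed, "peaks"))
  planted <- plant_motifs(sim$sequences, pk$peaks[[1]],
                          config$motif_consensus,
                          plant_prob = config$plant_prob,
                          positional_sd = config$plant_sd,
                          seed = derive_seed(config$seed, "motifs"))
  pops <- config$populations
  espec <- expression_spec(
    pops, n_genes = config$n_genes,
    planted = stats::setNames(
      rep(list(list(n = config$n_planted_genes,
                    fold = config$planted_fold, baseline_tpm = 50)),
          length(pops)), pops),
    replicates = config$replicates, dispersion = config$dispersion)
  ex <- simulate_expression(espec, sim$genes,
                            seed = derive_seed(config$seed, "expression"))

  dir.create(pj("truth"), showWarnings = FALSE)
  write_gene_table(sim$genes, pj("genes.tsv"))
  write_fasta(planted$sequences, pj("genome.fa"))
  for (f in names(pk$peaks)) write_peaks(pk$peaks[[f]],
                                         pj(sprintf("peaks_%s.bed", f)))
  write_peaks(pk$accessible$regions, pj("accessible.bed"))
  data.table::fwrite(pk$anchors, pj("truth", "anchors.tsv"), sep = "\t")
  data.table::fwrite(pk$truth, pj("truth", "peaks.tsv"), sep = "\t")
  data.table::fwrite(planted$truth, pj("truth", "motifs.tsv"), sep = "\t")
  data.table::fwrite(
    data.frame(population = rep(names(ex$truth),
                                lengths(ex$truth)),
               gene_id = unlist(ex$truth, use.names = FALSE)),
    pj("truth", "expression.tsv"), sep = "\t")

  ## ---- overlap + hotspots ----
  ovt <- overlap_table(pk$peaks, pk$accessible,
                       max_center_dist = config$max_center_dist)
  write_table_with_params(ovt, pj("overlap.tsv"),
                          list(max_center_dist = config$max_center_dist,
                               accessible_size = pk$accessible$total_size))
  min_f <- if (is.null(config$min_factors)) length(pk$peaks)
           else config$min_factors
  hs <- find_hotspots(pk$peaks, window = config$hotspot_window,
                      min_factors = min_f)
  write_table_with_params(as.data.frame(hs), pj("hotspots.tsv"),
                          list(window = config$hotspot_window,
                               min_factors = min_f,
                               grouping_rule = attr(hs, "grouping_rule")))

  ## ---- motif ----
  motif <- pwm_from_consensus(config$motif_consensus)
  motif$threshold <- pwm_threshold_from_pvalue(motif, config$motif_pvalue)
  occ <- scan_pwm(planted$sequences, motif)
  matched <- lapply(seq_len(config$n_matched_sets), function(i)
    matched_random_peaks(pk$peaks[[1]], sim$genes, sim$genome,
                         seed = derive_seed(config$seed,
                                            paste0("matched", i))))
  me <- motif_enrichment(pk$peaks[[1]], occ, matched,
                         window = config$motif_window)
  write_table_with_params(
    data.frame(motif = motif$name, n_a = me$n_a, n_am = me$n_am,
               n_m = me$n_m, p_m = me$p_m, coverage = me$coverage,
               p_value = me$p_value, neg_log10_p = me$neg_log10_p),
    pj("motif_enrichment.tsv"),
    list(window = config$motif_window, scan_pvalue = config$motif_pvalue,
         n_matched_sets = config$n_matched_sets,
         threshold = motif$threshold))

  ## ---- targets + category enrichment ----
  domains <- build_domains(sim$genes, sim$genome, mode = config$domain_mode,
                           flank = config$flank,
                           basal_up = config$basal_up,
                           basal_down = config$basal_down,
                           extension = config$extension)
  per_factor_targets <- lapply(pk$peaks, function(p)
    assign_targets(p, domains, sim$genes)$target_genes)
  core <- core_targets(per_factor_targets)
  writeLines(core, pj("core_targets.txt"))

  desets <- select_enriched_genes(ex$expr, pops[1], pops[2],
                                  fold = config$de_fold,
                                  min_tpm = config$de_min_tpm,
                                  alpha = config$de_alpha)
  popsets <- threshold_gene_sets(
    ex$expr,
    comparisons = list(progenitor = c(pops[1], pops[2]),
                       self_renewing = c(pops[2], pops[3]),
                       differentiating = c(pops[3], pops[2])),
    min_tpm = config$set_min_tpm, fold = config$set_fold)
  categories <- Filter(length, c(
    popsets, list(de_a = desets$a$gene_id, de_b = desets$b$gene_id)))
  sets_for_enrich <- pk$peaks
  if (nrow(hs) > 0) sets_for_enrich$hotspots <- hotspots_as_peaks(hs)
  cat_table <- category_enrichment_table(
    sets_for_enrich, categories, sim$genes, sim$genome, domains = domains,
    n_random = config$n_random,
    seed = derive_seed(config$seed, "region_enrichment"))
  write_table_with_params(cat_table, pj("category_enrichment.tsv"),
                          list(mode = config$domain_mode,
                               n_random = config$n_random,
                               flank = config$flank))

  uniq <- unique_targets_by_combination(per_factor_targets)
  frac <- category_fraction(uniq, categories, sim$genes$gene_id)
  write_table_with_params(frac, pj("category_fraction.tsv"),
                          list(categories = names(categories)))

  ## ---- rearrangement demo (bundled toy locus) ----
  toy <- toy_rearranged_locus()
  wt_contacts <- predict_contacts(toy$features, config$contact_max_range)
  rearr <- apply_rearrangement(toy$features, toy$plan)
  mut_contacts <- predict_contacts(rearr$features,
                                   config$contact_max_range)
  write_table_with_params(wt_contacts, pj("contacts_wildtype.tsv"),
                          list(max_range = config$contact_max_range))
  write_table_with_params(mut_contacts, pj("contacts_rearranged.tsv"),
                          list(max_range = config$contact_max_range))
  write_table_with_params(plan_summary(toy$plan), pj("plan_summary.tsv"),
                          list(order = toy$plan$order))

  invisible(list(sim = sim, peaks = pk, overlap = ovt, hotspots = hs,
                 motif = me, domains = domains, core_targets = core,
                 enriched = desets, categories = categories,
                 category_enrichment = cat_table,
                 category_fraction = frac,
                 contacts = list(wildtype = wt_contacts,
                                 rearranged = mut_contacts)))
}

#' Bundled toy rearranged locus
#'
#' A synthetic miniature of an inversion allele that rewires
#' enhancer-promoter contacts: on a 1 Mb toy chromosome the wild-type
#' order is `DE` (distal enhancer), `geneA` promoter, insulating
#' `boundary`, `geneB` promoter. `DE`-`geneA` is allowed; `DE`-`geneB`
#' is blocked by the boundary despite being the shorter-range pair one
#' might naively permit. The plan inverts a segment containing `geneA`,
#' the boundary, and `geneB` (breakpoint between `DE` and `geneA`), plus
#' two small deletions. On the rearranged axis `geneB` lands on the
#' enhancer's side of the boundary — a new, LONGER-range allowed contact
#' — while `geneA` is repositioned beyond the boundary and loses its
#' enhancer. Coordinates are illustrative, not genomic.
#'
#' @return list with `features` (`locus_features`) and `plan`
#'   (`rearrangement_plan`).
#' @export
toy_rearranged_locus <- function() {
  features <- locus_features(
    name = c("DE", "geneA_promoter", "boundary", "geneB_promoter",
             "geneA_body"),
    kind = c("enhancer", "promoter_tss", "boundary", "promoter_tss",
             "gene_body"),
    chrom = "chrT",
    start = c(99000, 199000, 249000, 259000, 201000),
    end = c(101000, 201000, 251000, 261000, 220000),
    strand = c("*", "+", "*", "+", "+"))
  plan <- rearrangement_plan(
    inversion = genomic_intervals("chrT", 150000, 500000),
    deletions = genomic_intervals("chrT", c(120000, 300000),
                                  c(120500, 300005)))
  list(features = features, plan = plan)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run-all` (both need `--config` or use the
#' defaults), plus `--seed` and `--out`. Exit codes: 0 ok, 1 user error,
#' 2 internal error. Used by the `cistromics` script in `exec/`.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit code, invisibly.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cistromics <simulate|run-all> [--config FILE] [--seed N]",
    "--out DIR")
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(0L))
  }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (!length(i)) return(default)
    if (i == length(args)) stop("missing value for ", flag, call. = FALSE)
    args[i + 1]
  }
  code <- tryCatch({
    if (!cmd %in% c("simulate", "run-all")) {
      message("unknown subcommand: ", cmd, "\n", usage)
      return(invisible(1L))
    }
    out <- opt("--out")
    if (is.null(out)) {
      message("--out is required\n", usage)
      return(invisible(1L))
    }
    cfg_path <- opt("--config")
    cfg <- if (is.null(cfg_path)) default_config() else read_config(cfg_path)
    seed <- opt("--seed")
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    if (cmd == "run-all") {
      run_pipeline(cfg, out)
    } else {
      sim <- simulate_genome(cfg$n_chroms, cfg$chrom_len, cfg$n_genes,
                             seed = derive_seed(cfg$seed, "genome"))
      spec <- cobinding_spec(cfg$factors, n_anchors = cfg$n_anchors,
                             n_specific = cfg$n_specific,
                             jitter_sd = cfg$jitter_sd,
                             width_range = cfg$width_range,
                             cobinding_matrix = cfg$cobinding_prob,
                             accessible_fraction = cfg$accessible_fraction)
      pk <- simulate_peaks(spec, sim$genome,
                           seed = derive_seed(cfg$seed, "peaks"))
      dir.create(file.path(out, "truth"), showWarnings = FALSE,
                 recursive = TRUE)
      write_gene_table(sim$genes, file.path(out, "genes.tsv"))
      write_fasta(sim$sequences, file.path(out, "genome.fa"))
      for (f in names(pk$peaks))
        write_peaks(pk$peaks[[f]],
                    file.path(out, sprintf("peaks_%s.bed", f)))
      write_peaks(pk$accessible$regions, file.path(out, "accessible.bed"))
      data.table::fwrite(pk$anchors, file.path(out, "truth", "anchors.tsv"),
                         sep = "\t")
      data.table::fwrite(pk$truth, file.path(out, "truth", "peaks.tsv"),
                         sep = "\t")
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(code)
}
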