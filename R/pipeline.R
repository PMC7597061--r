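#' Run the full classification pipeline
#'
#' Orchestrates the whole flow: read edges and gene sets, build the
#' network, extract the LCC, decompose the bow tie and driver nodes,
#' detect modules, restrict diseases and pathways to the LCC, screen
#' CATG-0, score the remaining diseases (IALS/WPS -> IS -> NIS),
#' cluster, cut, optionally refine, cross-tabulate against the
#' top-level classes, and run the overlapping-pair Fisher analysis.
#' Every stage writes a TSV into `out_dir` and a JSON manifest records
#' versions, seeds and input hashes; with fixed seeds a rerun is
#' bit-identical.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `edges` (edge-list TSV path) or `biogrid` (BioGRID tab file) plus
#'   `taxon`; `diseases`, `pathways` (gene-set TSV paths);
#'   `louvain_seed`, `tsne_seed` (optional; `NULL` skips the
#'   embedding), `k_max` (optional), `refine` (optional YAML override
#'   path), `out_dir`.
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  required <- c("diseases", "pathways", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("pipeline config is missing: ", paste(missing, collapse = ", "))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  louvain_seed <- if (is.null(config$louvain_seed)) 1L else
    as.integer(config$louvain_seed)
  taxon <- if (is.null(config$taxon)) 9606L else as.integer(config$taxon)

  stage <- function(name, expr) {
    res <- try(expr, silent = TRUE)
    if (inherits(res, "try-error")) {
      stop("pipeline stage '", name, "' failed: ",
           attr(res, "condition")$message, call. = FALSE)
    }
    res
  }

  inputs <- c(edges = config$edges, biogrid = config$biogrid,
              diseases = config$diseases, pathways = config$pathways)

  records <- stage("read", {
    if (!is.null(config$edges)) read_edge_list(config$edges, taxon = taxon)
    else if (!is.null(config$biogrid)) read_biogrid_tab(config$biogrid)
    else stop("config needs either `edges` or `biogrid`")
  })
  build <- stage("build", build_network(records, taxon = taxon))
  lcc <- stage("lcc", largest_weak_component(build$network))
  decomp <- stage("bow_tie", bow_tie(lcc))
  drivers <- stage("driver_nodes", driver_nodes(lcc))
  modules <- stage("modules", fast_unfolding(lcc, seed = louvain_seed))

  diseases <- stage("read_diseases", read_gene_sets(config$diseases, "disease"))
  pathways <- stage("read_pathways", read_gene_sets(config$pathways, "pathway"))
  diseases_lcc <- stage("restrict_diseases",
                        restrict_gene_sets(diseases, decomp$lcc))
  pathways_lcc <- stage("restrict_pathways",
                        restrict_gene_sets(pathways, decomp$lcc))

  catg0 <- stage("screen_catg0", screen_catg0(diseases_lcc, decomp))
  remaining <- stage("subset_remaining",
                     subset_gene_sets(diseases_lcc,
                                      catg0$remaining_disease_ids))
  scores <- stage("impact_scores",
                  impact_scores(lcc, remaining, pathways_lcc, modules))
  dm <- stage("distance", distance_matrix(scores))
  hc <- stage("ward", ward_cluster(dm))
  cut <- stage("cut", difference_vector_cut(hc, dm, k_max = config$k_max))
  prelim <- stage("assign", make_category_assignment(
    cut$labels, catg0$catg0_disease_ids))
  final <- if (!is.null(config$refine)) {
    stage("refine", apply_refinements(prelim, read_refinements(config$refine)))
  } else {
    prelim
  }

  # reference assignment from the collection's own top-level classes
  ref_labels <- setNames(
    lapply(seq_len(nrow(diseases_lcc$table)), function(i) {
      diseases_lcc$table$top_level_class[i]
    }), diseases_lcc$table$id)
  reference <- structure(list(labels = ref_labels,
                              n_categories = length(unique(unlist(ref_labels))),
                              provenance = "reference"),
                         class = "lamp_categories")
  xtab <- stage("crosstab", category_crosstab(final, reference))
  ora <- stage("overlap", overlap_analysis(diseases_lcc, final))

  tsne <- NULL
  if (!is.null(config$tsne_seed)) {
    tsne <- stage("tsne", tsne_embed(scores,
                                     seed = as.integer(config$tsne_seed)))
  }

  # --- outputs ------------------------------------------------------
  w <- function(df, file, seed = NULL) {
    write_lamp_table(df, file.path(out_dir, file), seed = seed,
                     inputs = inputs)
  }
  w(as.data.frame(build$report), "build_report.tsv")
  part_df <- data.frame(gene = decomp$lcc, stringsAsFactors = FALSE)
  part_df$part <- "other"
  part_df$part[part_df$gene %in% decomp$lscc] <- "LSCC"
  part_df$part[part_df$gene %in% decomp$up_lscc] <- "UP_LSCC"
  part_df$part[part_df$gene %in% decomp$down_lscc] <- "DOWN_LSCC"
  part_df$driver <- part_df$gene %in% drivers
  w(part_df, "bowtie_membership.tsv")
  w(data.frame(gene = names(modules$assignment),
               module = as.integer(modules$assignment),
               stringsAsFactors = FALSE),
    "modules.tsv", seed = louvain_seed)
  w(data.frame(disease = catg0$catg0_disease_ids, stringsAsFactors = FALSE),
    "catg0.tsv")
  nis_df <- data.frame(disease = rownames(scores$nis),
                       scores$nis, check.names = FALSE,
                       stringsAsFactors = FALSE)
  w(nis_df, "nis.tsv")
  lab_df <- data.frame(
    disease = names(final$labels),
    categories = vapply(final$labels, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  w(lab_df, "labels.tsv")
  ent_df <- data.frame(category = names(xtab$entropy_ab),
                       entropy_bits = as.numeric(xtab$entropy_ab),
                       stringsAsFactors = FALSE)
  w(ent_df, "entropy.tsv")
  xtab_df <- data.frame(category = rownames(xtab$composition_ab),
                        xtab$composition_ab, check.names = FALSE,
                        stringsAsFactors = FALSE)
  w(xtab_df, "crosstab.tsv")
  w(cbind(ora$table,
          odds_ratio = ora$fisher$odds_ratio,
          p_value = ora$fisher$p_value),
    "overlap.tsv")
  if (!is.null(tsne)) w(tsne, "tsne.tsv", seed = config$tsne_seed)

  manifest <- list(
    lamp_version = lamp_version(),
    louvain_seed = louvain_seed,
    tsne_seed = config$tsne_seed,
    taxon = taxon,
    inputs = as.list(inputs),
    input_md5 = as.list(tools::md5sum(unname(inputs))),
    n_nodes = build$report$n_nodes, n_edges = build$report$n_edges,
    n_lcc = length(decomp$lcc), n_lscc = length(decomp$lscc),
    n_driver = length(drivers), n_modules = modules$n_modules,
    n_diseases_working = n_gene_sets(diseases_lcc),
    n_catg0 = length(catg0$catg0_disease_ids),
    n_categories = final$n_categories,
    k_cut = cut$k)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(build = build, lcc = lcc, decomposition = decomp,
                 drivers = drivers, modules = modules,
                 diseases = diseases_lcc, pathways = pathways_lcc,
                 catg0 = catg0, scores = scores, distance = dm,
                 tree = hc, cut = cut, assignment = final,
                 crosstab = xtab, overlap = ora, tsne = tsne,
                 manifest = manifest))
}
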