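#' Read a feature table from disk
#'
#' Readers for the pipeline's tabular inputs. Counts and metadata are TSV;
#' metabolite intensities and hormone panels are CSV. The first column holds
#' feature ids; remaining columns are samples. Sample order and group labels
#' are taken from the metadata.
#'
#' @param path File path.
#' @param schema One of `counts_tsv`, `intensity_csv`, `hormone_csv`.
#' @param metadata Data.frame with columns `sample_id`, `group` (from
#'   [read_metadata()]).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, schema = c("counts_tsv", "intensity_csv", "hormone_csv"),
                               metadata) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (schema == "counts_tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"")
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature id in ", path, ": ", ids[duplicated(ids)][1L])
  }
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(raw[, -1L, drop = FALSE], is.numeric, logical(1)))[1L]
    stop("non-numeric cells in ", path, ", column '", colnames(mat)[bad], "'")
  }
  rownames(mat) <- ids
  missing_samples <- setdiff(metadata$sample_id, colnames(mat))
  extra_samples <- setdiff(colnames(mat), metadata$sample_id)
  if (length(missing_samples) || length(extra_samples)) {
    stop("sample-id mismatch in ", path,
         if (length(missing_samples)) paste0("; missing: ", paste(missing_samples, collapse = ", ")),
         if (length(extra_samples)) paste0("; unknown: ", paste(extra_samples, collapse = ", ")))
  }
  mat <- mat[, metadata$sample_id, drop = FALSE]
  kind <- switch(schema, counts_tsv = "counts", intensity_csv = "intensity",
                 hormone_csv = "hormone")
  feature_table(mat, metadata$group, kind)
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id` and `group`.
#' @return Data.frame with character columns `sample_id`, `group`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(md))) {
    stop("metadata must have columns sample_id and group: ", path)
  }
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata: ", path)
  md[, c("sample_id", "group")]
}

#' Read a pathway annotation table
#'
#' @param path TSV with columns `pathway_id` and `metabolite_id`, one
#'   membership per row.
#' @return Named list: pathway id -> character vector of metabolite ids.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("pathway_id", "metabolite_id") %in% names(ann))) {
    stop("annotation must have columns pathway_id and metabolite_id: ", path)
  }
  split(ann$metabolite_id, ann$pathway_id)
}

#' Write a feature table to disk
#'
#' Inverse of [read_feature_table()]: TSV for counts, CSV otherwise, feature
#' ids in the first column.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  sep <- if (table$kind == "counts") "\t" else ","
  df <- data.frame(feature_id = table$feature_ids, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Write a synthetic study to a directory
#'
#' Writes the four tables (genus TSV; fecal/serum/hormone CSV), the
#' metadata TSV, and the planted truth as JSON, in the formats
#' [run_pipeline()] consumes.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return (Invisibly) the named vector of paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genera = file.path(dir, "genus_counts.tsv"),
    fecal = file.path(dir, "fecal_metabolites.csv"),
    serum = file.path(dir, "serum_metabolites.csv"),
    hormones = file.path(dir, "hormones.csv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_feature_table(study$genera, paths[["genera"]])
  write_feature_table(study$fecal, paths[["fecal"]])
  write_feature_table(study$serum, paths[["serum"]])
  write_feature_table(study$hormones, paths[["hormones"]])
  utils::write.table(study$metadata, paths[["metadata"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(study$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Screen hormones for group differences
#'
#' Per-hormone unpaired two-tailed t-test (Student by default) between the
#' two groups.
#'
#' @param table A hormone [feature_table()] with a 2-level group.
#' @param alpha Significance level (default 0.05).
#' @param variant `"student"` or `"welch"`.
#' @return Data.frame: feature_id, statistic, p, direction, significant.
#' @export
screen_hormones <- function(table, alpha = 0.05, variant = "student") {
  stopifnot(inherits(table, "feature_table"))
  g <- table$group
  if (nlevels(g) != 2L) stop("exactly 2 groups required")
  idx0 <- which(g == levels(g)[1L])
  idx1 <- which(g == levels(g)[2L])
  rows <- lapply(seq_along(table$feature_ids), function(i) {
    res <- ttest_two_sample(table$values[i, idx1], table$values[i, idx0],
                            variant = variant)
    data.frame(
      feature_id = table$feature_ids[i],
      statistic = res$statistic, p = res$p_value,
      direction = if (res$statistic >= 0) "up" else "down",
      significant = res$p_value < alpha,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Run the full screen-then-mediate pipeline
#'
#' Executes, in order: hormone t-tests; microbiome screen (rarefaction to
#' the minimum sample depth by default, alpha diversity with Mann-Whitney
#' group tests, CSS normalization, Bray-Curtis PCoA, LEfSe-style LDA
#' screen on the rarefied counts); metabolome screen per compartment
#' (missingness filter, OPLS-DA, VIP + t-test selection, optional pathway
#' enrichment); then bidirectional causal mediation over the differential
#' candidates. All randomness (rarefaction, CV folds, bootstraps,
#' quasi-Bayesian draws) flows from `seed`.
#'
#' @param hormones,genera Hormone and genus [feature_table()]s.
#' @param metabolite_tables Named list of intensity [feature_table()]s
#'   (e.g. `list(fecal = ..., serum = ...)`).
#' @param annotation Optional pathway annotation (named list), applied to
#'   each compartment's selected metabolites.
#' @param alpha,lda_threshold,vip_threshold,max_missing_frac Thresholds
#'   (defaults 0.05, 3, 1, 0.6).
#' @param rarefaction_depth Depth (default: minimum sample total).
#' @param n_sims Quasi-Bayesian draws per triad (default 1000).
#' @param seed Master seed.
#' @param outdir Optional directory; when given, all stage outputs are
#'   written there as TSV/JSON.
#' @return List: `hormone_screen`, `alpha` (+ group tests), `distance`,
#'   `ordination`, `lda`, `metabolome` (per compartment: vips, model
#'   summary, enrichment), `mediation`, and `report` (per-stage feature
#'   counts, thresholds, seed).
#' @export
run_pipeline <- function(hormones, genera, metabolite_tables, annotation = NULL,
                         alpha = 0.05, lda_threshold = 3.0, vip_threshold = 1.0,
                         max_missing_frac = 0.6, rarefaction_depth = NULL,
                         n_sims = 1000, seed = 1, outdir = NULL) {
  stopifnot(inherits(hormones, "feature_table"), inherits(genera, "feature_table"),
            is.list(metabolite_tables), length(metabolite_tables) >= 1)

  # 1. hormones
  horm <- screen_hormones(hormones, alpha = alpha)

  # 2. microbiome
  if (is.null(rarefaction_depth)) rarefaction_depth <- min(colSums(genera$values))
  rare <- rarefy(genera, rarefaction_depth, seed = seed + 1L)
  adiv <- alpha_diversity(rare)
  g <- rare$group
  alpha_tests <- do.call(rbind, lapply(c("shannon", "chao1", "observed", "simpson"),
    function(metric) {
      res <- mann_whitney(adiv[[metric]][g == levels(g)[2L]],
                          adiv[[metric]][g == levels(g)[1L]])
      data.frame(metric = metric, statistic = res$statistic, p = res$p_value,
                 method = res$method, stringsAsFactors = FALSE)
    }))
  css <- css_normalize(rare)
  dmat <- bray_curtis(css)
  ord <- pcoa(dmat)
  lda <- lda_effect_screen(rare, alpha = alpha, lda_threshold = lda_threshold,
                           seed = seed + 2L)

  # 3. metabolome, per compartment
  met_results <- list()
  for (nm in names(metabolite_tables)) {
    scr <- screen_metabolites(metabolite_tables[[nm]], alpha = alpha,
                              vip_threshold = vip_threshold,
                              max_missing_frac = max_missing_frac,
                              seed = seed + 3L)
    enr <- if (!is.null(annotation)) {
      pathway_enrichment(scr$vips$feature_id[scr$vips$selected], annotation,
                         scr$vips$feature_id)
    } else NULL
    met_results[[nm]] <- list(vips = scr$vips, model = scr$model, t2 = scr$t2,
                              n_filtered = scr$n_filtered, enrichment = enr)
  }
  all_mets <- do.call(rbind, lapply(names(met_results), function(nm) {
    v <- met_results[[nm]]$vips
    v$compartment <- nm
    v
  }))

  # 4. mediation over the differential candidates, both directions
  met_combined <- combine_metabolite_tables(metabolite_tables)
  candidates <- list(
    hormones = horm$feature_id[horm$significant],
    genera = lda$feature_id[lda$passed],
    metabolites = all_mets$feature_id[all_mets$selected]
  )
  mediation <- screen_triples(hormones, rare, met_combined, candidates,
                              direction = "both", alpha = alpha,
                              n_sims = n_sims, seed = seed + 4L)

  report <- list(
    seed = seed,
    thresholds = list(alpha = alpha, lda_threshold = lda_threshold,
                      vip_threshold = vip_threshold,
                      max_missing_frac = max_missing_frac,
                      rarefaction_depth = rarefaction_depth, n_sims = n_sims),
    counts = list(
      hormones = c(input = nrow(hormones$values), significant = sum(horm$significant)),
      genera = c(input = nrow(genera$values), passed = sum(lda$passed)),
      metabolites = c(
        input = sum(vapply(metabolite_tables, function(t) nrow(t$values), numeric(1))),
        tested = nrow(all_mets), selected = sum(all_mets$selected)
      ),
      triads = c(evaluated = nrow(mediation), gated = sum(mediation$gated),
                 reported = sum(mediation$reported))
    )
  )

  out <- list(hormone_screen = horm, alpha = adiv, alpha_tests = alpha_tests,
              distance = dmat, ordination = ord, lda = lda,
              metabolome = met_results, mediation = mediation, report = report)

  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

# Internal: row-concatenate metabolite tables (e.g. fecal + serum, or the
# merged positive/negative ESI modes) into one feature table. Feature ids
# must already be distinct across tables.
combine_metabolite_tables <- function(tables) {
  vals <- do.call(rbind, lapply(tables, function(t) t$values))
  if (anyDuplicated(rownames(vals))) {
    stop("metabolite feature ids must be unique across compartments")
  }
  feature_table(vals, tables[[1L]]$group, "intensity")
}

write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wt(out$hormone_screen, "hormone_screen.tsv")
  wt(out$alpha, "alpha_diversity.tsv")
  wt(out$alpha_tests, "alpha_diversity_tests.tsv")
  utils::write.table(out$distance, file.path(outdir, "bray_curtis.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(out$ordination$coordinates,
                     file.path(outdir, "pcoa_coordinates.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  wt(out$lda, "lda_screen.tsv")
  for (nm in names(out$metabolome)) {
    wt(out$metabolome[[nm]]$vips, paste0("metabolites_", nm, ".tsv"))
    m <- out$metabolome[[nm]]$model
    jsonlite::write_json(
      list(r2x = m$r2x, r2y = m$r2y, q2 = m$q2, n_ortho = m$n_ortho,
           t2_crit = out$metabolome[[nm]]$t2$t2_crit),
      file.path(outdir, paste0("opls_", nm, ".json")),
      auto_unbox = TRUE, digits = NA
    )
    if (!is.null(out$metabolome[[nm]]$enrichment)) {
      wt(out$metabolome[[nm]]$enrichment, paste0("enrichment_", nm, ".tsv"))
    }
  }
  wt(out$mediation, "mediation.tsv")
  mediation_edge_list(out$mediation, file.path(outdir, "mediation_edges.json"))
  jsonlite::write_json(out$report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
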