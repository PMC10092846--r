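#' Default transform map for nest-size models
#'
#' Nest dimensions, clutch size, body size, nest-site height and
#' nestling period are log-transformed; precipitation and absolute
#' latitude are square-root transformed; temperature uses a signed
#' square root (sign(x) sqrt(|x|)) so sub-zero breeding-season means
#' stay defined. All continuous variables are then mean-centred and
#' scaled to unit SD.
#'
#' @return Named character vector usable as \code{transform_map}.
#' @export
default_transforms <- function() {
  c(outer_volume = "log", inner_volume = "log", full_volume = "log",
    external_diameter = "log", internal_diameter = "log",
    external_height = "log", internal_height = "log",
    rim_thickness = "log",
    body_mass = "log", clutch_size = "log", nest_height = "log",
    nestling_period = "log",
    abs_latitude = "sqrt", precipitation = "sqrt",
    temperature = "signed_sqrt")
}

#' Assemble the record-level analysis table
#'
#' Joins measurement records (with volumes), the species life-history
#' table and the per-species geographic summary into one row per
#' measurement record, and derives model columns: \code{abs_latitude},
#' \code{hemisphere_south}, \code{insular} (large-threshold flag),
#' \code{source_literature} and \code{rim_thickness} ((D - d) / 2 when
#' both rim diameters are present).
#'
#' @param measurements Measurement table with volume columns (see
#'   \code{\link{add_volumes}}).
#' @param life_history \code{data.frame} keyed by \code{species_id};
#'   recognised columns include \code{body_mass}, \code{clutch_size},
#'   \code{nest_ground}, \code{nest_vegetation}, \code{nest_cliff},
#'   \code{cavity_nester}, \code{nest_height}, \code{migratory},
#'   \code{nest_builder} ("female", "mainly_female", "both", ...),
#'   \code{care_system} ("biparental", "female_only", "helpers"),
#'   \code{nestling_period}.
#' @param geo_summaries Output of \code{\link{species_geo_summary}} (or
#'   a compatible \code{data.frame}), keyed by \code{species_id}.
#' @return \code{data.frame} of class \code{"analysis_table"} with a
#'   \code{counts} attribute (records and species at input and after the
#'   join).
#' @export
assemble <- function(measurements, life_history, geo_summaries) {
  key <- paste(measurements$species_id, measurements$site_label)
  if (anyDuplicated(key))
    stop("duplicate (species_id, site_label) keys: ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  if (anyDuplicated(life_history$species_id))
    stop("duplicate species_id in life_history")
  tab <- merge(measurements, life_history, by = "species_id", all.x = TRUE)
  tab <- merge(tab, geo_summaries, by = "species_id", all.x = TRUE)
  unmatched <- setdiff(measurements$species_id,
                       intersect(life_history$species_id,
                                 geo_summaries$species_id))
  tab$source_literature <- as.numeric(tab$source == "literature")
  if (!is.null(tab$midpoint_lat)) {
    tab$abs_latitude <- abs(tab$midpoint_lat)
    tab$hemisphere_south <- as.numeric(tab$hemisphere == "south")
  }
  if (!is.null(tab$insular_large_threshold))
    tab$insular <- as.numeric(tab$insular_large_threshold)
  if (!is.null(tab$mean_temperature) && is.null(tab$temperature))
    tab$temperature <- tab$mean_temperature
  if (!is.null(tab$mean_precipitation) && is.null(tab$precipitation))
    tab$precipitation <- tab$mean_precipitation
  if (all(c("D1", "d1") %in% names(tab)) && !"rim_thickness" %in% names(tab)) {
    Dm <- rowMeans(tab[, intersect(paste0("D", 1:4), names(tab)),
                       drop = FALSE], na.rm = TRUE)
    dm <- rowMeans(tab[, intersect(paste0("d", 1:4), names(tab)),
                       drop = FALSE], na.rm = TRUE)
    tab$rim_thickness <- (Dm - dm) / 2
  }
  attr(tab, "counts") <- list(
    records_in = nrow(measurements),
    records_joined = nrow(tab),
    species = length(unique(tab$species_id)),
    species_unmatched = unmatched)
  class(tab) <- c("analysis_table", "data.frame")
  tab
}

#' Default model suite for the nest-size analysis
#'
#' Named model specifications for each response analysed: the outer,
#' inner and full volumes, the four linear dimensions, rim thickness, a
#' builder-identity contrast on the biparental-care subset, and the
#' nestling-period model (response nestling period, outer volume among
#' the predictors, one row per species). Obligate cavity nesters are
#' excluded from every outer-dimension model; helper and female-only
#' care systems are excluded from the builder contrast.
#'
#' @param predictors Base predictor set for the dimension models.
#' @return Named list of \code{\link{model_spec}} objects, each
#'   carrying \code{exclude_cavity} / \code{subset_biparental} /
#'   \code{per_species} attributes consumed by \code{\link{model_table}}.
#' @export
default_model_suite <- function(predictors = c("source_literature",
                                               "body_mass", "clutch_size",
                                               "temperature", "precipitation",
                                               "abs_latitude",
                                               "hemisphere_south", "insular",
                                               "nest_ground",
                                               "nest_vegetation",
                                               "nest_cliff", "migratory")) {
  tm <- default_transforms()
  binary <- c(source_literature = "binary", hemisphere_south = "binary",
              insular = "binary", nest_ground = "binary",
              nest_vegetation = "binary", nest_cliff = "binary",
              migratory = "binary", builder_both = "binary")
  mk <- function(response, fixed, exclude_cavity = FALSE,
                 subset_biparental = FALSE, per_species = FALSE,
                 random = c("phylogeny", "species")) {
    sp <- model_spec(response, fixed,
                     fixed_types = binary[intersect(names(binary), fixed)],
                     random_terms = random,
                     transform_map = tm[intersect(names(tm),
                                                  c(response, fixed))])
    attr(sp, "exclude_cavity") <- exclude_cavity
    attr(sp, "subset_biparental") <- subset_biparental
    attr(sp, "per_species") <- per_species
    sp
  }
  outer_like <- function(resp) mk(resp, predictors, exclude_cavity = TRUE)
  inner_like <- function(resp) mk(resp, predictors)
  list(
    outer_volume = outer_like("outer_volume"),
    inner_volume = inner_like("inner_volume"),
    full_volume = outer_like("full_volume"),
    external_diameter = outer_like("external_diameter"),
    internal_diameter = inner_like("internal_diameter"),
    external_height = outer_like("external_height"),
    internal_height = inner_like("internal_height"),
    rim_thickness = outer_like("rim_thickness"),
    builder_contrast = mk("outer_volume",
                          c("builder_both", predictors),
                          exclude_cavity = TRUE, subset_biparental = TRUE),
    nestling_period = mk("nestling_period",
                         c("outer_volume", "body_mass", "temperature",
                           "nest_ground", "nest_vegetation", "nest_cliff"),
                         exclude_cavity = TRUE, per_species = TRUE,
                         random = "phylogeny")
  )
}

#' Build the per-model table with exclusions and complete cases
#'
#' Applies the model's exclusion rules (cavity nesters out of
#' outer-dimension models; builder models restricted to biparental-care
#' species with female or biparental builders, male-built nests
#' excluded; per-species models averaged to one row per species), then
#' keeps complete cases on the model variables.
#'
#' @param table An \code{\link{assemble}}d analysis table.
#' @param spec A \code{\link{model_spec}} from the suite.
#' @return \code{data.frame} ready for \code{\link{build_design}}, with
#'   a \code{counts} attribute logging rows surviving each step.
#' @export
model_table <- function(table, spec) {
  counts <- list(input = nrow(table))
  tab <- table
  if (isTRUE(attr(spec, "exclude_cavity")) && "cavity_nester" %in% names(tab)) {
    tab <- tab[!(tab$cavity_nester %in% c(1, TRUE)), , drop = FALSE]
    counts$after_cavity_exclusion <- nrow(tab)
  }
  if (isTRUE(attr(spec, "subset_biparental"))) {
    if (!all(c("care_system", "nest_builder") %in% names(tab)))
      stop("builder models need care_system and nest_builder columns")
    tab <- tab[tab$care_system == "biparental" &
                 tab$nest_builder %in% c("female", "mainly_female", "both"), ,
               drop = FALSE]
    tab$builder_both <- as.numeric(tab$nest_builder == "both")
    counts$after_care_subset <- nrow(tab)
  }
  need <- c("species_id", spec$response, spec$fixed_terms)
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing model columns: ",
                         paste(miss, collapse = ", "))
  tab <- tab[stats::complete.cases(tab[, need]), need, drop = FALSE]
  counts$complete_cases <- nrow(tab)
  if (isTRUE(attr(spec, "per_species"))) {
    num <- setdiff(need, "species_id")
    agg <- stats::aggregate(tab[num], by = list(species_id = tab$species_id),
                            FUN = mean)
    tab <- agg
    counts$per_species_rows <- nrow(tab)
  }
  counts$species <- length(unique(tab$species_id))
  attr(tab, "counts") <- counts
  tab
}

#' Transform and standardise model columns
#'
#' Convenience wrapper: applies a \code{\link{model_spec}}'s transform
#' map and standardisation to a table and returns the model-ready
#' columns (used by reporting; \code{\link{build_design}} performs the
#' same operation internally when fitting).
#'
#' @param table \code{data.frame} containing the model columns.
#' @param spec A \code{\link{model_spec}}.
#' @return \code{data.frame} with transformed response and predictors.
#' @export
apply_transforms <- function(table, spec) {
  out <- data.frame(row.names = seq_len(nrow(table)))
  for (v in c(spec$response, spec$fixed_terms)) {
    x <- .apply_transform(table[[v]], spec$transform_map[[v]], v)
    if (v != spec$response && spec$fixed_types[[v]] == "continuous" &&
        spec$standardize)
      x <- .standardize(x, spec$sd_divisor)
    out[[v]] <- x
  }
  out
}

#' Run the full model suite
#'
#' For each model: builds the model table, checks variance inflation of
#' the non-interaction predictors, pools the Gibbs sampler over the
#' tree sample and summarises. Runs failing convergence checks are
#' flagged \code{converged = FALSE} in their summary, never silently
#' accepted.
#'
#' @param table An assembled analysis table.
#' @param suite Named list of model specs
#'   (\code{\link{default_model_suite}}).
#' @param priors A \code{\link{prior_spec}}.
#' @param settings An \code{\link{mcmc_settings}}.
#' @param trees List of trees.
#' @param ess_floor Convergence floor on per-parameter ESS.
#' @return Named list per model: \code{summary} (a
#'   \code{"model_summary"}), \code{sample} (pooled draws), \code{vif},
#'   \code{counts}.
#' @export
run_suite <- function(table, suite, priors = prior_spec(),
                      settings = mcmc_settings(), trees, ess_floor = 100) {
  out <- list()
  for (nm in names(suite)) {
    spec <- suite[[nm]]
    tab <- model_table(table, spec)
    vt <- apply_transforms(tab, spec)
    vifs <- vif(as.matrix(vt[, spec$fixed_terms, drop = FALSE]))
    sample <- multi_tree_run(tab, spec, priors, settings, trees)
    out[[nm]] <- list(summary = summarize_posterior(sample, ess_floor),
                      sample = sample, vif = vifs,
                      counts = attr(tab, "counts"))
  }
  out
}

#' Write tidy posterior draws
#'
#' @param sample A \code{"posterior_sample"}.
#' @param path Output TSV (columns draw, tree_index, parameter, value).
#' @export
write_draws <- function(sample, path) {
  B <- sample$beta_draws
  long <- data.frame(
    draw = rep(seq_len(nrow(B)), ncol(B) + 3L),
    tree_index = rep(sample$tree_index, ncol(B) + 3L),
    parameter = rep(c(colnames(B), "var_phylo", "var_species",
                      "var_residual"), each = nrow(B)),
    value = c(B, sample$var_phylo_draws, sample$var_species_draws,
              sample$var_residual_draws))
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a suite summary as TSV and JSON
#'
#' @param results \code{\link{run_suite}} output.
#' @param tsv_path,json_path Output paths (either may be NULL).
#' @return Invisibly, the summary data.frame.
#' @export
write_suite_summary <- function(results, tsv_path = NULL, json_path = NULL) {
  rows <- do.call(rbind, lapply(names(results), function(nm) {
    f <- results[[nm]]$summary$fixed
    f$model <- nm
    f$conditional_r2 <- results[[nm]]$summary$conditional_r2
    f$converged <- results[[nm]]$summary$converged
    f
  }))
  if (!is.null(tsv_path))
    utils::write.table(rows, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(rows, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(rows)
}
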