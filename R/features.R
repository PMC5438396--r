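#' Cortical roughness of a vertex-wise thickness field
#'
#' Roughness of a region is the standard deviation of cortical thickness
#' across its surface vertices — the sample SD with the n-1 denominator,
#' matching the ThickStd convention of parcellation stats tables. An
#' optional mean-normalized variant (coefficient of variation) is exposed
#' but never the default.
#'
#' @param vertex_thickness Numeric vector of per-vertex thickness (mm),
#'   length at least 2, finite and non-negative.
#' @param normalized If `TRUE`, return SD / mean (dimensionless) instead of
#'   the plain SD.
#' @return Roughness in mm (or a ratio when `normalized`).
#' @examples
#' compute_roughness(c(2.0, 4.0)) # sqrt(2)
#' @export
compute_roughness <- function(vertex_thickness, normalized = FALSE) {
  if (length(vertex_thickness) < 2) {
    stop("insufficient data: roughness needs at least 2 vertices")
  }
  if (any(!is.finite(vertex_thickness))) {
    stop("vertex thickness values must all be finite")
  }
  if (any(vertex_thickness < 0)) {
    stop("vertex thickness values must be non-negative")
  }
  s <- stats::sd(vertex_thickness)
  if (normalized) s / mean(vertex_thickness) else s
}

# Pooled SD across member regions: sqrt(sum((n_i-1) s_i^2) / (sum n_i - k)).
pooled_sd <- function(sds, ns) {
  k <- length(sds)
  sqrt(sum((ns - 1) * sds^2) / (sum(ns) - k))
}

#' Assemble a subject's schema feature vector from parsed stats tables
#'
#' Resolves every schema descriptor from the parsed stats: cortical gray
#' volumes and thickness summaries from the parcellation tables, other
#' volumes from the segmentation table and its header measures, ICV-ratio
#' features as raw volume / estimated intracranial volume, and lobar
#' composites as vertex-count-weighted means (thickness) and pooled SDs
#' (roughness) over the packaged member-region lists. A subject with any
#' unresolvable feature is rejected rather than imputed.
#'
#' @param stats Named list with elements `lh_aparc`, `rh_aparc`, `aseg`,
#'   each an `fs_stats` object from [parse_stats_table()].
#' @param schema Feature schema tibble, see [et_schema()].
#' @param subject_id Optional subject identifier carried into the output.
#' @return One-row tibble: `subject_id`, `icv`, then one column per schema
#'   feature in schema order.
#' @export
assemble_features <- function(stats, schema, subject_id = NA_character_) {
  validate_schema(schema)
  need <- c("lh_aparc", "rh_aparc", "aseg")
  if (!all(need %in% names(stats))) {
    stop("stats must be a named list with lh_aparc, rh_aparc and aseg")
  }
  aseg <- stats$aseg
  icv <- stats_measure(aseg, "EstimatedTotalIntraCranialVol")
  if (is.na(icv) &&
      any(schema$feature_type == "volume_icv_ratio")) {
    stop("configuration error: schema contains ICV-ratio features but no ",
         "EstimatedTotalIntraCranialVol measure is present")
  }

  nv <- region_vertex_counts()
  lobes <- lobe_members()
  sub <- subcortical_structures()
  mid <- midline_structures()
  seg_map <- c(
    stats::setNames(paste0("Left-", sub$aseg_stem),
                    paste0("lh-", sub$code, "-volume")),
    stats::setNames(paste0("Right-", sub$aseg_stem),
                    paste0("rh-", sub$code, "-volume")),
    stats::setNames(mid$aseg_name, paste0(mid$code, "-volume"))
  )
  measure_map <- c(
    "lh-cerebral-white-matter-volume" = "lhCerebralWhiteMatter",
    "rh-cerebral-white-matter-volume" = "rhCerebralWhiteMatter",
    "total-gray-volume" = "TotalGray"
  )

  aparc_col <- function(hemi, region, col) {
    tab <- stats[[paste0(hemi, "_aparc")]]$regions
    i <- match(region, tab$StructName)
    if (is.na(i)) return(NA_real_)
    tab[[col]][[i]]
  }

  lobar_value <- function(hemi, lobe, type) {
    members <- lobes[[lobe]]
    ta <- vapply(members, function(r) aparc_col(hemi, r, "ThickAvg"),
                 numeric(1))
    if (any(is.na(ta))) return(NA_real_)
    w <- nv[members]
    if (type == "thickness_mean") {
      sum(w * ta) / sum(w)
    } else {
      ts <- vapply(members, function(r) aparc_col(hemi, r, "ThickStd"),
                   numeric(1))
      if (any(is.na(ts))) return(NA_real_)
      pooled_sd(ts, w)
    }
  }

  resolve_one <- function(name, hemisphere, region, feature_type) {
    if (feature_type == "volume_icv_ratio") {
      raw <- resolve_one(sub("-volume/ICV$", "-volume", name), hemisphere,
                         region, "volume")
      return(raw / icv)
    }
    if (feature_type == "volume") {
      if (name %in% names(seg_map)) {
        tab <- aseg$regions
        i <- match(seg_map[[name]], tab$StructName)
        return(if (is.na(i)) NA_real_ else tab$Volume_mm3[[i]])
      }
      if (name %in% names(measure_map)) {
        return(stats_measure(aseg, measure_map[[name]]))
      }
      return(aparc_col(hemisphere, region, "GrayVol"))
    }
    is_lobe <- grepl("-lobe$", region)
    lobe <- sub("-lobe$", "", region)
    if (feature_type == "thickness_mean") {
      if (is_lobe) lobar_value(hemisphere, lobe, "thickness_mean")
      else aparc_col(hemisphere, region, "ThickAvg")
    } else {
      if (is_lobe) lobar_value(hemisphere, lobe, "thickness_roughness")
      else aparc_col(hemisphere, region, "ThickStd")
    }
  }

  values <- purrr::pmap_dbl(
    schema[c("name", "hemisphere", "region", "feature_type")],
    function(name, hemisphere, region, feature_type)
      resolve_one(name, hemisphere, region, feature_type)
  )
  if (any(!is.finite(values))) {
    stop("assembly error: unresolvable features: ",
         paste(utils::head(schema$name[!is.finite(values)], 10),
               collapse = ", "))
  }
  out <- tibble::as_tibble(
    c(list(subject_id = subject_id, icv = icv),
      stats::setNames(as.list(values), schema$name)),
    .name_repair = "minimal"
  )
  out
}

#' Extract a subject's feature vector from a stats directory
#'
#' Convenience wrapper: parses `lh.aparc.stats`, `rh.aparc.stats` and
#' `aseg.stats` under `stats_dir` and assembles the schema feature vector.
#' A packaged synthetic example lives at
#' `system.file("extdata", "synthetic_subject", package = "etminer")`.
#'
#' @param stats_dir Directory containing the three stats files.
#' @param schema Feature schema tibble.
#' @param subject_id Identifier for the output row; defaults to the
#'   directory name.
#' @return One-row tibble as from [assemble_features()].
#' @export
extract_subject <- function(stats_dir, schema = et_schema(),
                            subject_id = basename(stats_dir)) {
  stats <- list(
    lh_aparc = parse_stats_table(file.path(stats_dir, "lh.aparc.stats")),
    rh_aparc = parse_stats_table(file.path(stats_dir, "rh.aparc.stats")),
    aseg = parse_stats_table(file.path(stats_dir, "aseg.stats"))
  )
  assemble_features(stats, schema, subject_id = subject_id)
}

#' Assemble a cohort table from per-subject features and metadata
#'
#' Binds per-subject feature rows with a cohort metadata table into the
#' rectangular subjects-by-features interchange table the rest of the
#' pipeline operates on. Feature columns are schema-ordered; the schema is
#' attached as the `"schema"` attribute for later subsetting by feature
#' type.
#'
#' @param features Data frame with one row per subject: `subject_id` plus
#'   schema feature columns (as produced by [assemble_features()] or the
#'   synthetic generator).
#' @param metadata Data frame with `subject_id`, `group` (values among
#'   `"control"`, `"ET"`, `"unknown"`) and optional covariates.
#' @param schema Feature schema tibble; defaults to [et_schema()].
#' @return A cohort tibble: metadata columns, then schema-ordered feature
#'   columns; class `et_cohort`.
#' @export
build_cohort_table <- function(features, metadata, schema = et_schema()) {
  validate_schema(schema)
  if (nrow(features) == 0) stop("empty subject list")
  if (anyDuplicated(features$subject_id)) {
    stop("duplicate subject_id in features")
  }
  if (anyDuplicated(metadata$subject_id)) {
    stop("duplicate subject_id in metadata")
  }
  missing_meta <- setdiff(features$subject_id, metadata$subject_id)
  if (length(missing_meta) > 0) {
    stop("subjects present in features but not metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  if (!all(schema$name %in% names(features))) {
    stop("features lack schema columns: ",
         paste(utils::head(setdiff(schema$name, names(features)), 5),
               collapse = ", "))
  }
  if ("group" %in% names(metadata) &&
      !all(metadata$group %in% c("control", "ET", "unknown"))) {
    stop("group labels must be among control, ET, unknown")
  }
  meta_cols <- names(metadata)
  extra <- intersect(setdiff(names(features), schema$name),
                     c("subject_id", "icv"))
  out <- dplyr::inner_join(metadata, features[c(extra, schema$name)],
                           by = "subject_id")
  out <- out[c(meta_cols, setdiff(extra, meta_cols), schema$name)]
  out <- tibble::as_tibble(out, .name_repair = "minimal")
  attr(out, "schema") <- schema
  class(out) <- c("et_cohort", class(out))
  out
}

# Schema attached to a cohort (falls back to the packaged default).
cohort_schema <- function(cohort) {
  sch <- attr(cohort, "schema")
  if (is.null(sch)) et_schema() else sch
}

#' Feature columns of a cohort by ranked subset
#'
#' @param cohort Cohort tibble from [build_cohort_table()] or
#'   [generate_cohort()].
#' @param subset One of `"all"`, `"thickness"`, `"roughness"`, `"volume"`.
#' @return Character vector of feature column names.
#' @export
cohort_features <- function(cohort, subset = "all") {
  intersect(subset_features(cohort_schema(cohort), subset), names(cohort))
}

#' Write a cohort feature table as TSV with a JSON schema sidecar
#'
#' @param cohort Cohort tibble.
#' @param path Output TSV path; a `.json` sidecar with the schema and
#'   generation provenance is written next to it.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sidecar <- list(
    schema = cohort_schema(cohort),
    n_subjects = nrow(cohort),
    provenance = attr(cohort, "provenance")
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a cohort feature table written by [write_cohort_tsv()]
#'
#' @param path TSV path.
#' @return Cohort tibble with schema attribute restored from the sidecar
#'   when present.
#' @export
read_cohort_tsv <- function(path) {
  out <- tibble::as_tibble(
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE),
    .name_repair = "minimal"
  )
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "schema") <- tibble::as_tibble(sc$schema)
  }
  class(out) <- c("et_cohort", class(out))
  out
}
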