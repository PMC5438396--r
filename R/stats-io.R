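#' Parse a FreeSurfer-style stats table
#'
#' Reads the plain-text stats dialect emitted by cortical parcellation and
#' volumetric segmentation pipelines: `#`-prefixed comment headers,
#' `# Measure key, shortname, description, value, units` lines, a
#' `# ColHeaders ...` declaration, and whitespace-delimited data rows.
#'
#' @param x Path to a stats file, or a character vector of its lines.
#' @return An object of class `fs_stats`: a list with `regions` (a tibble,
#'   one row per parcellation/segmentation unit, columns as declared by
#'   ColHeaders) and `measures` (a tibble with `key`, `value`, `units`).
#'   Header measures are keyed by their canonical (first) name, e.g.
#'   `EstimatedTotalIntraCranialVol`.
#' @export
parse_stats_table <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else if (length(x) == 1 && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    x
  }
  lines <- lines[nzchar(trimws(lines))]
  is_comment <- startsWith(trimws(lines), "#")

  header <- trimws(lines[is_comment])
  colhead_line <- grep("^# *ColHeaders", header, value = TRUE)
  if (length(colhead_line) == 0) {
    stop("stats table format error: no '# ColHeaders' line found")
  }
  col_names <- strsplit(sub("^# *ColHeaders +", "", colhead_line[[1]]),
                        "[[:space:]]+")[[1]]

  measure_lines <- grep("^# *Measure ", header, value = TRUE)
  measures <- purrr::map_dfr(measure_lines, function(ln) {
    parts <- trimws(strsplit(sub("^# *Measure +", "", ln), ",")[[1]])
    # key, shortname, description, value, units
    val <- suppressWarnings(as.numeric(parts[length(parts) - 1]))
    tibble::tibble(key = parts[[1]], value = val,
                   units = parts[[length(parts)]])
  })
  if (nrow(measures) == 0) {
    measures <- tibble::tibble(key = character(), value = numeric(),
                               units = character())
  }

  data_idx <- which(!is_comment)
  rows <- lapply(data_idx, function(i) {
    strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
  })
  if (length(rows) > 0) {
    nf <- lengths(rows)
    if (any(nf != length(col_names))) {
      bad <- data_idx[which(nf != length(col_names))[1]]
      stop("stats table format error: line ", bad, " has ", nf[nf != length(col_names)][1],
           " fields, expected ", length(col_names))
    }
  }
  mat <- do.call(rbind, rows)
  regions <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                               .name_repair = "minimal")
  if (nrow(regions) > 0) names(regions) <- col_names else {
    regions <- tibble::as_tibble(
      stats::setNames(rep(list(character()), length(col_names)), col_names)
    )
  }
  # every column except structure-name-like ones is numeric
  name_cols <- intersect(c("StructName", "SegId"), col_names)
  num_cols <- setdiff(col_names, "StructName")
  for (cn in num_cols) {
    parsed <- suppressWarnings(as.numeric(regions[[cn]]))
    bad <- which(is.na(parsed) & !is.na(regions[[cn]]))
    if (length(bad) > 0) {
      stop("stats table row error: non-numeric value '", regions[[cn]][bad[1]],
           "' in column ", cn, " at data line ", data_idx[bad[1]])
    }
    regions[[cn]] <- parsed
  }
  structure(list(regions = regions, measures = measures),
            class = "fs_stats")
}

#' @export
print.fs_stats <- function(x, ...) {
  cat("<fs_stats> ", nrow(x$regions), " rows, ", nrow(x$measures),
      " header measures\n", sep = "")
  invisible(x)
}

#' Look up a header measure from a parsed stats table
#'
#' @param stats An `fs_stats` object.
#' @param key Canonical measure key, e.g. `"EstimatedTotalIntraCranialVol"`.
#' @return Numeric value, or `NA` if absent.
#' @export
stats_measure <- function(stats, key) {
  i <- match(key, stats$measures$key)
  if (is.na(i)) NA_real_ else stats$measures$value[[i]]
}

format_stats_header <- function(measures, col_headers) {
  c(
    "# Table of structural measures (synthetic)",
    sprintf("# Measure %s, %s, %s, %.6f, %s",
            measures$key, measures$key, measures$key, measures$value,
            measures$units),
    paste("# ColHeaders", paste(col_headers, collapse = " "))
  )
}

#' Write FreeSurfer-dialect stats files for one subject
#'
#' Emits `lh.aparc.stats`, `rh.aparc.stats` and `aseg.stats` under
#' `out_dir/subject_id/`, parseable by [parse_stats_table()] and
#' assemblable by [assemble_features()]. Regional rows are written from the
#' subject's schema feature values; lobar composite features are derived
#' quantities and are not written.
#'
#' @param subject A one-row data frame (or named list) of schema feature
#'   values, including a `subject_id` and an `icv` entry.
#' @param schema Feature schema tibble, see [et_schema()].
#' @param out_dir Output directory; created if needed.
#' @return The subject directory path, invisibly.
#' @export
write_stats_files <- function(subject, schema, out_dir) {
  subject <- as.list(subject)
  sid <- subject$subject_id
  if (is.null(sid)) stop("subject must carry a subject_id")
  icv <- subject$icv
  if (is.null(icv) || is.na(icv)) stop("subject must carry an icv value")
  dir <- file.path(out_dir, sid)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  subj_val <- function(f) {
    v <- subject[[f]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  nv <- region_vertex_counts()
  for (h in c("lh", "rh")) {
    regions <- intersect(
      dk_regions(),
      schema$region[schema$feature_type == "thickness_mean" &
                      schema$hemisphere == h]
    )
    ta <- vapply(regions, function(r)
      subj_val(paste0(h, "-", r, "-thickness")), numeric(1))
    ts <- vapply(regions, function(r)
      subj_val(paste0(h, "-", r, "-roughness")), numeric(1))
    gv <- vapply(regions, function(r)
      subj_val(paste0(h, "-", r, "-volume")), numeric(1))
    gv[is.na(gv)] <- 0
    area <- gv / pmax(ta, 0.1)
    meas <- tibble::tibble(
      key = "EstimatedTotalIntraCranialVol", value = icv, units = "mm^3"
    )
    hdr <- format_stats_header(
      meas, c("StructName", "NumVert", "SurfArea", "GrayVol", "ThickAvg",
              "ThickStd")
    )
    body <- sprintf("%-28s %6d %10.1f %10.1f %8.4f %8.4f",
                    regions, as.integer(nv[regions]), area, gv, ta, ts)
    writeLines(c(hdr, body), file.path(dir, paste0(h, ".aparc.stats")))
  }

  sub <- subcortical_structures()
  mid <- midline_structures()
  seg_names <- c(paste0("Left-", sub$aseg_stem),
                 paste0("Right-", sub$aseg_stem), mid$aseg_name)
  seg_feats <- c(paste0("lh-", sub$code, "-volume"),
                 paste0("rh-", sub$code, "-volume"),
                 paste0(mid$code, "-volume"))
  in_schema <- seg_feats %in% schema$name
  seg_names <- seg_names[in_schema]
  seg_feats <- seg_feats[in_schema]
  vol <- vapply(seg_feats, subj_val, numeric(1))
  meas <- tibble::tibble(
    key = c("EstimatedTotalIntraCranialVol", "lhCerebralWhiteMatter",
            "rhCerebralWhiteMatter", "TotalGray"),
    value = c(icv,
              subj_val("lh-cerebral-white-matter-volume"),
              subj_val("rh-cerebral-white-matter-volume"),
              subj_val("total-gray-volume")),
    units = "mm^3"
  )
  meas <- meas[!is.na(meas$value), , drop = FALSE]
  hdr <- format_stats_header(
    meas, c("Index", "SegId", "NVoxels", "Volume_mm3", "StructName")
  )
  body <- sprintf("%4d %5d %8d %12.4f %s",
                  seq_along(seg_names), seq_along(seg_names) + 10L,
                  as.integer(round(vol)), vol, seg_names)
  writeLines(c(hdr, body), file.path(dir, "aseg.stats"))
  invisible(dir)
}
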