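#' Desikan-Killiany cortical parcellation regions
#'
#' The 34 gyral-based cortical regions per hemisphere that regional
#' thickness and gray-volume features are defined over.
#'
#' @return Character vector of 34 region codes.
#' @export
dk_regions <- function() {
  c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal"
  )
}

#' Lobar composite membership
#'
#' Member regions of the four lobar composite features (frontal, temporal,
#' parietal, occipital). Cingulate regions and the insula belong to no lobe.
#' Lobar thickness is the vertex-count-weighted mean of member regions;
#' lobar roughness pools member variances (see [assemble_features()]).
#'
#' @return Named list of character vectors keyed by lobe.
#' @export
lobe_members <- function() {
  list(
    frontal = c(
      "caudalmiddlefrontal", "frontalpole", "lateralorbitofrontal",
      "medialorbitofrontal", "paracentral", "parsopercularis",
      "parsorbitalis", "parstriangularis", "precentral",
      "rostralmiddlefrontal", "superiorfrontal"
    ),
    temporal = c(
      "bankssts", "entorhinal", "fusiform", "inferiortemporal",
      "middletemporal", "parahippocampal", "superiortemporal",
      "temporalpole", "transversetemporal"
    ),
    parietal = c(
      "inferiorparietal", "postcentral", "precuneus", "superiorparietal",
      "supramarginal"
    ),
    occipital = c("cuneus", "lateraloccipital", "lingual", "pericalcarine")
  )
}

# Reference vertex counts per cortical region (one hemisphere); used for
# lobar weighting and for emitted stats files. Magnitudes follow typical
# adult parcellations.
region_vertex_counts <- function() {
  c(
    bankssts = 1700, caudalanteriorcingulate = 1200,
    caudalmiddlefrontal = 3800, cuneus = 2500, entorhinal = 700,
    frontalpole = 400, fusiform = 5000, inferiorparietal = 8200,
    inferiortemporal = 5600, insula = 3500, isthmuscingulate = 1600,
    lateraloccipital = 8300, lateralorbitofrontal = 4400, lingual = 5100,
    medialorbitofrontal = 3100, middletemporal = 5400, paracentral = 2500,
    parahippocampal = 1200, parsopercularis = 2800, parsorbitalis = 1100,
    parstriangularis = 2300, pericalcarine = 2400, postcentral = 7000,
    posteriorcingulate = 2000, precentral = 8400, precuneus = 6300,
    rostralanteriorcingulate = 1300, rostralmiddlefrontal = 7600,
    superiorfrontal = 11200, superiorparietal = 8600,
    superiortemporal = 6100, supramarginal = 6500, temporalpole = 800,
    transversetemporal = 800
  )
}

# Reference mean gray volumes (mm^3) per cortical region, one hemisphere.
region_gray_volume_means <- function() {
  c(
    bankssts = 3300, caudalanteriorcingulate = 2100,
    caudalmiddlefrontal = 7000, cuneus = 3800, entorhinal = 2000,
    frontalpole = 1100, fusiform = 10200, inferiorparietal = 15800,
    inferiortemporal = 11300, insula = 7100, isthmuscingulate = 2800,
    lateraloccipital = 12800, lateralorbitofrontal = 8100, lingual = 7800,
    medialorbitofrontal = 5600, middletemporal = 11700, paracentral = 3900,
    parahippocampal = 2300, parsopercularis = 5100, parsorbitalis = 2500,
    parstriangularis = 4300, pericalcarine = 2600, postcentral = 10400,
    posteriorcingulate = 3500, precentral = 14000, precuneus = 10600,
    rostralanteriorcingulate = 2600, rostralmiddlefrontal = 14200,
    superiorfrontal = 22800, superiorparietal = 13900,
    superiortemporal = 12400, supramarginal = 11700, temporalpole = 2400,
    transversetemporal = 1200
  )
}

# Bilateral subcortical segmentation structures with reference mean volumes
# (mm^3, per side) and the corresponding FreeSurfer aseg StructName stem.
subcortical_structures <- function() {
  tibble::tibble(
    code = c(
      "lateral-ventricle", "inf-lat-vent", "thalamus", "caudate", "putamen",
      "pallidum", "hippocampus", "amygdala", "accumbens", "ventral-dc",
      "choroid-plexus"
    ),
    aseg_stem = c(
      "Lateral-Ventricle", "Inf-Lat-Vent", "Thalamus-Proper", "Caudate",
      "Putamen", "Pallidum", "Hippocampus", "Amygdala", "Accumbens-area",
      "VentralDC", "choroid-plexus"
    ),
    mean_volume = c(8500, 350, 7200, 3600, 4900, 1800, 4000, 1600, 600,
                    3900, 1600)
  )
}

# Midline / unpaired segmentation structures.
midline_structures <- function() {
  tibble::tibble(
    code = c(
      "third-ventricle", "fourth-ventricle", "brain-stem", "csf",
      "cc-posterior", "cc-mid-posterior", "cc-central", "cc-mid-anterior",
      "cc-anterior"
    ),
    aseg_name = c(
      "3rd-Ventricle", "4th-Ventricle", "Brain-Stem", "CSF", "CC_Posterior",
      "CC_Mid_Posterior", "CC_Central", "CC_Mid_Anterior", "CC_Anterior"
    ),
    mean_volume = c(1100, 1800, 20500, 1000, 950, 450, 480, 480, 880)
  )
}

# Structures whose ICV-normalized ratio variant is part of the schema:
# all bilateral subcortical structures plus the ventricular system,
# brain stem, CSF and total gray.
icv_ratio_codes <- function() {
  bilateral <- subcortical_structures()$code
  c(
    paste0("lh-", bilateral), paste0("rh-", bilateral),
    "third-ventricle", "fourth-ventricle", "brain-stem", "csf", "total-gray"
  )
}

#' The packaged 281-feature structural schema
#'
#' One row per feature of the case-control morphometry analysis:
#' 129 volume-typed features (68 cortical gray volumes, 31 segmentation
#' volumes, lh/rh cerebral white matter, total gray, and 27 ICV-ratio
#' variants), 76 regional/lobar mean-thickness features and 76 roughness
#' features (the SD of cortical thickness over a region's vertices),
#' following the Desikan-Killiany parcellation with four lobar composites
#' per hemisphere.
#'
#' @return A tibble with columns `name` (unique feature key), `hemisphere`
#'   (`"lh"`, `"rh"` or `"none"`), `region`, `feature_type`
#'   (`"volume"`, `"volume_icv_ratio"`, `"thickness_mean"` or
#'   `"thickness_roughness"`) and `units` (`"mm^3"`, `"ratio"`, `"mm"`).
#' @examples
#' sch <- et_schema()
#' dplyr::count(sch, feature_type)
#' @export
et_schema <- function() {
  regions <- dk_regions()
  lobes <- paste0(names(lobe_members()), "-lobe")
  thick_units <- function(rs, hemi, type) {
    tibble::tibble(
      name = paste0(hemi, "-", rs, "-",
                    if (type == "thickness_mean") "thickness" else "roughness"),
      hemisphere = hemi, region = rs, feature_type = type, units = "mm"
    )
  }
  thick <- dplyr::bind_rows(lapply(c("lh", "rh"), function(h) {
    dplyr::bind_rows(
      thick_units(c(regions, lobes), h, "thickness_mean"),
      thick_units(c(regions, lobes), h, "thickness_roughness")
    )
  }))

  cortical_vol <- dplyr::bind_rows(lapply(c("lh", "rh"), function(h) {
    tibble::tibble(
      name = paste0(h, "-", regions, "-volume"),
      hemisphere = h, region = regions, feature_type = "volume",
      units = "mm^3"
    )
  }))

  sub <- subcortical_structures()
  sub_vol <- dplyr::bind_rows(lapply(c("lh", "rh"), function(h) {
    tibble::tibble(
      name = paste0(h, "-", sub$code, "-volume"),
      hemisphere = h, region = sub$code, feature_type = "volume",
      units = "mm^3"
    )
  }))

  mid <- midline_structures()
  mid_vol <- tibble::tibble(
    name = paste0(mid$code, "-volume"),
    hemisphere = "none", region = mid$code, feature_type = "volume",
    units = "mm^3"
  )

  global_vol <- tibble::tibble(
    name = c("lh-cerebral-white-matter-volume",
             "rh-cerebral-white-matter-volume", "total-gray-volume"),
    hemisphere = c("lh", "rh", "none"),
    region = c("cerebral-white-matter", "cerebral-white-matter",
               "total-gray"),
    feature_type = "volume", units = "mm^3"
  )

  ratio_codes <- icv_ratio_codes()
  ratios <- tibble::tibble(
    name = paste0(ratio_codes, "-volume/ICV"),
    hemisphere = ifelse(startsWith(ratio_codes, "lh-"), "lh",
                        ifelse(startsWith(ratio_codes, "rh-"), "rh", "none")),
    region = sub("^(lh|rh)-", "", ratio_codes),
    feature_type = "volume_icv_ratio", units = "ratio"
  )

  out <- dplyr::bind_rows(cortical_vol, sub_vol, mid_vol, global_vol,
                          ratios, thick)
  stopifnot(!anyDuplicated(out$name))
  out
}

#' Validate a feature schema
#'
#' Checks the structural invariants every schema must satisfy: unique
#' names, known feature types, and hemisphere tags on thickness features.
#'
#' @param schema A tibble as returned by [et_schema()].
#' @return The schema, invisibly; errors on violation.
#' @export
validate_schema <- function(schema) {
  stopifnot(is.data.frame(schema))
  req <- c("name", "hemisphere", "region", "feature_type", "units")
  missing <- setdiff(req, names(schema))
  if (length(missing) > 0) {
    stop("schema lacks columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(schema$name)) {
    stop("schema feature names must be unique")
  }
  ok_types <- c("volume", "volume_icv_ratio", "thickness_mean",
                "thickness_roughness")
  if (!all(schema$feature_type %in% ok_types)) {
    stop("unknown feature_type in schema")
  }
  thick <- schema$feature_type %in% c("thickness_mean", "thickness_roughness")
  if (!all(schema$hemisphere[thick] %in% c("lh", "rh"))) {
    stop("thickness-typed features must carry hemisphere lh or rh")
  }
  invisible(schema)
}

# Names of schema features belonging to a ranked subset.
subset_features <- function(schema, subset = c("all", "thickness",
                                               "roughness", "volume")) {
  subset <- match.arg(subset)
  keep <- switch(subset,
    all = rep(TRUE, nrow(schema)),
    thickness = schema$feature_type == "thickness_mean",
    roughness = schema$feature_type == "thickness_roughness",
    volume = schema$feature_type %in% c("volume", "volume_icv_ratio")
  )
  schema$name[keep]
}
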