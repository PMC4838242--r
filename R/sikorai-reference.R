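#' Registry of the 22 measured morphometric traits
#'
#' Canonical, ordered registry of the 22 continuous traits recorded on ant
#' workers (all linear measurements in micrometres), together with their
#' published measurement repeatability (average-measure intraclass
#' correlation from double measurement of 14 specimens). `CS`, the absolute
#' cephalic size, is the arithmetic mean of `CL` and `CWb`; it is derived,
#' never measured, and therefore not part of the registry.
#'
#' @return A data.frame with columns `code`, `description` and
#'   `repeatability_R`, one row per trait, in canonical column order.
#' @examples
#' traitRegistry()$code
#' @export
traitRegistry <- function() {
  data.frame(
    code = c("CL", "CW", "CWb", "PoOC", "SL", "EL", "FRS", "MW", "PSTI",
             "PEW", "PPW", "SPBA", "SPTI", "ML", "MPST", "NOH", "NOL",
             "PPL", "SPST", "PEH", "PEL", "PPH"),
    description = c(
      "Maximum cephalic length in median line",
      "Maximum head width including compound eyes",
      "Maximum head capsule width excluding compound eyes",
      "Postocular distance",
      "Maximum straight-line scape length",
      "Maximum compound eye diameter",
      "Frontal carina distance",
      "Mesosoma (pronotum) width, spines excluded",
      "Apical distance of pronotal spines, dorsal view",
      "Maximum petiole width, dorsal view",
      "Maximum postpetiole width, dorsal view",
      "Minimum propodeal spine distance at base",
      "Apical propodeal spine distance, dorsal view",
      "Mesosoma length (Weber's length)",
      "Propodeal spiracle to posteroventral metapleuron corner",
      "Maximum petiolar node height, lateral view",
      "Petiolar node length, lateral view",
      "Postpetiole length",
      "Propodeal spine length from spiracle center",
      "Maximum petiole height",
      "Diagonal petiole length, lateral view",
      "Maximum postpetiole height, lateral view"),
    repeatability_R = c(0.998, 0.999, 0.998, 0.997, 0.998, 0.929, 0.982,
                        0.998, 0.994, 0.996, 0.994, 0.993, 0.994, 0.998,
                        0.989, 0.958, 0.981, 0.975, 0.994, 0.989, 0.991,
                        0.991),
    stringsAsFactors = FALSE
  )
}

#' Trait codes in canonical order
#' @return Character vector of the 22 trait codes.
#' @export
traitCodes <- function() traitRegistry()$code

#' Metadata column names of the specimen-table CSV dialect
#' @return Character vector of the metadata header names preceding the trait
#'   columns: `casent`, `species`, `long`, `lat`, `dendro-name`.
#' @export
metadataColumns <- function() c("casent", "species", "long", "lat", "dendro-name")

# Ratio set used in the published per-species summary table: CS plus 21
# ratios (three cephalic ratios with non-CS denominators, then trait/CS).
.summaryRatioNames <- function() {
  c("CS", "PoOC/CL", "CL/CW", "CL/CWb",
    paste0(c("FRS", "SL", "EL", "MW", "PSTI", "PEW", "PPW", "SPBA", "SPTI",
             "ML", "PEL", "NOL", "MPST", "PEH", "NOH", "PPH", "SPST", "PPL"),
           "/CS"))
}

#' Published per-species morphometric summary of the sikorai group
#'
#' The per-species summary statistics for the eight species of the Malagasy
#' *Nesomyrmex sikorai* group, as printed in the source revision: sample
#' size, absolute cephalic size CS (micrometres) and 21 body-ratio indices,
#' each with mean, standard deviation, minimum and maximum, computed over
#' individuals. These values serve as reference input for realistic
#' simulations ([sikoraiTraitMeans()]) and for exercising the
#' identification key; they are transcription of published statistics, not
#' output of this package.
#'
#' @return A data.frame with columns `species`, `n`, `statistic` (one of
#'   the ratio names returned by the summary, e.g. `"CS"`, `"SL/CS"`),
#'   `mean`, `sd`, `min`, `max`.
#' @export
sikoraiReferenceTable <- function() {
  sp <- sikoraiSpecies()
  n  <- c(83L, 18L, 7L, 9L, 24L, 36L, 9L, 41L)
  # statistic x species matrices, transcribed column-by-column
  # (order: excelsior, modestus, reticulatus, retusispinosus, rugosus,
  #  sikorai, striatus, tamatavensis)
  stats <- .summaryRatioNames()
  mean <- c(
    736, 0.458, 1.169, 1.271, 0.291, 0.822, 0.230, 0.625, 0.611, 0.231,
    0.354, 0.225, 0.252, 1.379, 0.528, 0.357, 0.419, 0.296, 0.172, 0.272,
    0.279, 0.253,
    796, 0.453, 1.131, 1.216, 0.295, 0.771, 0.234, 0.647, 0.657, 0.223,
    0.341, 0.236, 0.251, 1.308, 0.499, 0.332, 0.404, 0.309, 0.179, 0.297,
    0.236, 0.235,
    511, 0.462, 1.105, 1.151, 0.320, 0.704, 0.241, 0.639, 0.629, 0.235,
    0.370, 0.254, 0.266, 1.252, 0.441, 0.266, 0.391, 0.327, 0.132, 0.280,
    0.233, 0.246,
    812, 0.483, 1.089, 1.170, 0.294, 0.838, 0.237, 0.679, 0.659, 0.240,
    0.390, 0.240, 0.322, 1.362, 0.543, 0.352, 0.420, 0.319, 0.185, 0.271,
    0.430, 0.263,
    732, 0.473, 1.155, 1.237, 0.289, 0.811, 0.228, 0.639, 0.648, 0.236,
    0.335, 0.218, 0.261, 1.346, 0.511, 0.340, 0.409, 0.297, 0.173, 0.268,
    0.287, 0.235,
    822, 0.488, 1.041, 1.169, 0.292, 0.828, 0.212, 0.675, 0.665, 0.269,
    0.370, 0.253, 0.299, 1.352, 0.516, 0.361, 0.423, 0.306, 0.173, 0.271,
    0.269, 0.239,
    842, 0.460, 1.048, 1.155, 0.288, 0.794, 0.219, 0.671, 0.666, 0.243,
    0.362, 0.242, 0.244, 1.379, 0.513, 0.339, 0.416, 0.304, 0.173, 0.288,
    0.241, 0.241,
    699, 0.433, 1.107, 1.155, 0.329, 0.798, 0.258, 0.705, 0.739, 0.243,
    0.363, 0.244, 0.303, 1.422, 0.544, 0.369, 0.427, 0.312, 0.181, 0.267,
    0.388, 0.246)
  sd <- c(
    34.3, 0.008, 0.030, 0.033, 0.007, 0.019, 0.008, 0.015, 0.015, 0.018,
    0.015, 0.020, 0.025, 0.025, 0.017, 0.015, 0.012, 0.011, 0.010, 0.012,
    0.020, 0.017,
    27.6, 0.008, 0.015, 0.020, 0.006, 0.020, 0.008, 0.015, 0.013, 0.007,
    0.009, 0.007, 0.012, 0.017, 0.013, 0.011, 0.009, 0.009, 0.009, 0.016,
    0.010, 0.008,
    25.7, 0.011, 0.026, 0.019, 0.009, 0.016, 0.011, 0.009, 0.015, 0.007,
    0.016, 0.017, 0.014, 0.015, 0.014, 0.010, 0.011, 0.016, 0.010, 0.022,
    0.013, 0.013,
    50.0, 0.010, 0.037, 0.048, 0.007, 0.018, 0.008, 0.018, 0.017, 0.014,
    0.017, 0.013, 0.013, 0.021, 0.018, 0.013, 0.010, 0.011, 0.013, 0.007,
    0.018, 0.009,
    35.9, 0.011, 0.020, 0.024, 0.006, 0.020, 0.005, 0.024, 0.023, 0.017,
    0.014, 0.019, 0.029, 0.023, 0.016, 0.013, 0.009, 0.008, 0.006, 0.016,
    0.016, 0.009,
    34.0, 0.016, 0.019, 0.021, 0.009, 0.018, 0.007, 0.013, 0.014, 0.020,
    0.011, 0.017, 0.019, 0.027, 0.013, 0.013, 0.010, 0.016, 0.011, 0.008,
    0.015, 0.011,
    41.3, 0.010, 0.016, 0.025, 0.004, 0.010, 0.008, 0.009, 0.013, 0.009,
    0.007, 0.018, 0.023, 0.008, 0.010, 0.013, 0.009, 0.006, 0.010, 0.021,
    0.012, 0.007,
    29.3, 0.009, 0.016, 0.017, 0.007, 0.014, 0.008, 0.017, 0.018, 0.014,
    0.013, 0.014, 0.020, 0.021, 0.012, 0.018, 0.009, 0.011, 0.008, 0.013,
    0.015, 0.008)
  min <- c(
    671, 0.437, 1.108, 1.209, 0.278, 0.786, 0.210, 0.591, 0.573, 0.206,
    0.321, 0.183, 0.198, 1.326, 0.490, 0.326, 0.383, 0.271, 0.149, 0.245,
    0.240, 0.200,
    743, 0.438, 1.097, 1.179, 0.287, 0.740, 0.217, 0.632, 0.636, 0.213,
    0.326, 0.225, 0.226, 1.279, 0.485, 0.312, 0.384, 0.288, 0.166, 0.262,
    0.220, 0.226,
    472, 0.449, 1.080, 1.125, 0.310, 0.679, 0.224, 0.624, 0.608, 0.222,
    0.339, 0.235, 0.244, 1.229, 0.424, 0.254, 0.372, 0.301, 0.122, 0.254,
    0.220, 0.227,
    731, 0.464, 1.002, 1.070, 0.285, 0.812, 0.225, 0.646, 0.621, 0.219,
    0.358, 0.219, 0.293, 1.339, 0.521, 0.325, 0.402, 0.300, 0.165, 0.260,
    0.400, 0.253,
    650, 0.450, 1.112, 1.189, 0.277, 0.784, 0.219, 0.601, 0.605, 0.200,
    0.308, 0.182, 0.191, 1.295, 0.484, 0.320, 0.393, 0.284, 0.161, 0.239,
    0.253, 0.214,
    748, 0.451, 0.998, 1.126, 0.276, 0.780, 0.201, 0.654, 0.636, 0.228,
    0.348, 0.215, 0.256, 1.265, 0.490, 0.329, 0.405, 0.278, 0.152, 0.248,
    0.221, 0.211,
    775, 0.441, 1.022, 1.117, 0.282, 0.779, 0.209, 0.659, 0.649, 0.229,
    0.351, 0.204, 0.191, 1.365, 0.503, 0.319, 0.394, 0.290, 0.155, 0.255,
    0.219, 0.234,
    634, 0.411, 1.079, 1.119, 0.318, 0.773, 0.243, 0.663, 0.708, 0.208,
    0.338, 0.221, 0.273, 1.362, 0.518, 0.327, 0.407, 0.281, 0.165, 0.240,
    0.364, 0.223)
  max <- c(
    839, 0.477, 1.245, 1.382, 0.312, 0.872, 0.246, 0.679, 0.662, 0.267,
    0.394, 0.272, 0.310, 1.450, 0.565, 0.403, 0.447, 0.330, 0.194, 0.300,
    0.352, 0.292,
    834, 0.466, 1.149, 1.256, 0.307, 0.808, 0.250, 0.695, 0.686, 0.238,
    0.358, 0.248, 0.269, 1.344, 0.530, 0.358, 0.424, 0.322, 0.196, 0.311,
    0.254, 0.252,
    545, 0.476, 1.146, 1.180, 0.335, 0.720, 0.255, 0.654, 0.650, 0.242,
    0.386, 0.275, 0.284, 1.269, 0.459, 0.279, 0.404, 0.346, 0.147, 0.312,
    0.257, 0.266,
    921, 0.498, 1.127, 1.233, 0.302, 0.862, 0.251, 0.700, 0.678, 0.262,
    0.415, 0.259, 0.332, 1.402, 0.575, 0.370, 0.434, 0.333, 0.205, 0.285,
    0.459, 0.282,
    781, 0.493, 1.191, 1.277, 0.300, 0.852, 0.235, 0.679, 0.692, 0.278,
    0.356, 0.256, 0.310, 1.405, 0.534, 0.372, 0.432, 0.319, 0.186, 0.294,
    0.314, 0.250,
    890, 0.511, 1.079, 1.226, 0.312, 0.862, 0.224, 0.698, 0.691, 0.326,
    0.391, 0.287, 0.341, 1.412, 0.537, 0.388, 0.452, 0.346, 0.196, 0.287,
    0.301, 0.270,
    889, 0.472, 1.073, 1.192, 0.294, 0.813, 0.232, 0.686, 0.686, 0.253,
    0.373, 0.260, 0.266, 1.390, 0.532, 0.355, 0.427, 0.312, 0.183, 0.315,
    0.260, 0.252,
    750, 0.449, 1.135, 1.182, 0.347, 0.832, 0.284, 0.736, 0.780, 0.270,
    0.385, 0.282, 0.350, 1.460, 0.576, 0.410, 0.444, 0.330, 0.194, 0.312,
    0.430, 0.265)
  data.frame(
    species = rep(sp, each = length(stats)),
    n = rep(n, each = length(stats)),
    statistic = rep(stats, times = length(sp)),
    mean = mean, sd = sd, min = min, max = max,
    stringsAsFactors = FALSE
  )
}

#' Species of the sikorai group
#' @return Character vector of the eight species epithets, alphabetical.
#' @export
sikoraiSpecies <- function() {
  c("excelsior", "modestus", "reticulatus", "retusispinosus",
    "rugosus", "sikorai", "striatus", "tamatavensis")
}

#' Reconstruct per-species trait means from the published ratio summary
#'
#' Converts the published per-species summary (CS plus 21 ratio means) back
#' to mean values of the 22 measured traits in micrometres. The algebra is
#' exact: with `r` the CL/CWb ratio and `CS = (CL + CWb)/2`,
#' `CL = 2 CS r / (1 + r)` and `CWb = 2 CS / (1 + r)`; `CW = CL / (CL/CW)`;
#' `PoOC = CL * (PoOC/CL)`; every remaining trait is `CS * (trait/CS)`.
#'
#' @return Numeric matrix, species (8) x traits (22), in micrometres, with
#'   species epithets as row names and canonical trait codes as column names.
#' @examples
#' round(sikoraiTraitMeans()["reticulatus", c("CL", "CWb", "SL")])
#' @export
sikoraiTraitMeans <- function() {
  ref <- sikoraiReferenceTable()
  sp <- sikoraiSpecies()
  codes <- traitCodes()
  out <- matrix(NA_real_, length(sp), length(codes),
                dimnames = list(sp, codes))
  for (s in sp) {
    v <- ref[ref$species == s, ]
    stat <- function(nm) v$mean[match(nm, v$statistic)]
    cs <- stat("CS")
    r <- stat("CL/CWb")
    cl <- 2 * cs * r / (1 + r)
    cwb <- 2 * cs / (1 + r)
    cw <- cl / stat("CL/CW")
    pooc <- cl * stat("PoOC/CL")
    out[s, "CL"] <- cl
    out[s, "CWb"] <- cwb
    out[s, "CW"] <- cw
    out[s, "PoOC"] <- pooc
    rest <- setdiff(codes, c("CL", "CWb", "CW", "PoOC"))
    out[s, rest] <- cs * vapply(paste0(rest, "/CS"), stat, numeric(1))
  }
  out
}

#' Typical collection elevations per species
#'
#' Approximate mean collection elevations (metres above sea level) of the
#' eight species, taken from the published distribution accounts; used by the
#' simulator to attach an advisory elevation covariate (relevant to the
#' final key couplet separating the high-ground from the lowland member of
#' the excelsior complex).
#'
#' @return Named numeric vector of elevations in metres.
#' @export
sikoraiElevations <- function() {
  c(excelsior = 1007, modestus = 514, reticulatus = 94,
    retusispinosus = 390, rugosus = 360, sikorai = 1054,
    striatus = 800, tamatavensis = 550)
}

#' Nest counts per species in the revision's material
#'
#' Numbers of nest series per species used as the default unbalanced design
#' of the simulator (the study measured 227 workers from 180 nests; the
#' excelsior sample alone spans 58 nests).
#'
#' @return Named integer vector of nest counts.
#' @export
sikoraiNestCounts <- function() {
  c(excelsior = 58L, modestus = 18L, reticulatus = 7L,
    retusispinosus = 9L, rugosus = 23L, sikorai = 28L,
    striatus = 9L, tamatavensis = 32L)
}

#' Locate the study's specimen-level supplementary table
#'
#' The revision's raw specimen-level table (227 workers x 22 traits in
#' micrometres, CSV in the dialect read by readSpecimenTable()) is third-party supplementary material and
#' is not distributed with this package. Place a copy at
#' `inst/extdata/sikorai_specimens.csv` (before installation) or at
#' `<library>/MorphoPart/extdata/sikorai_specimens.csv` (after) to enable the
#' real-data reproduction tests and analyses.
#'
#' @return The file path, or `NA_character_` when the file is absent.
#' @export
sikoraiSpecimenTablePath <- function() {
  p <- system.file("extdata", "sikorai_specimens.csv", package = "MorphoPart")
  if (nzchar(p) && file.exists(p)) p else NA_character_
}
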