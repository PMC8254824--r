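#' Desikan-Killiany cortical parcels used by the synthetic cohort
#'
#' Returns the 34 bilateral Desikan-Killiany regions of interest (ROIs) with
#' the attributes the cohort generator uses as defaults: a typical
#' left-right-average parcel volume (mm^3, scaled so that twice their sum
#' matches a total cortical volume of 398,508 mm^3 in the early 70s), an
#' annual percentage change, the standardized loading of each ROI's latent
#' slope on the general factor of cortical change, and two alternative
#' groupings: \code{change_group} (1 = fronto-temporal, 2 = occipito-parietal)
#' drives the group-factor structure of slopes, while \code{level_group}
#' (a dorsal/ventral split) drives the deliberately different group structure
#' of cross-sectional levels.
#'
#' @return A data.frame with 34 rows and columns \code{name}, \code{lobe},
#'   \code{change_group}, \code{level_group}, \code{volume},
#'   \code{pct_change}, \code{g_loading}, \code{grp_loading}.
#' @export
#' @examples
#' head(dk_rois())
dk_rois <- function() {
  x <- utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
name lobe change_group level_group volume pct_change g_loading grp_loading
bankssts temporal 1 2 2500 -0.90 0.72 0.46
caudalanteriorcingulate cingulate 1 1 1900 -0.62 0.62 0.56
caudalmiddlefrontal frontal 1 1 6300 -1.05 0.72 0.50
cuneus occipital 2 1 3200 -0.85 0.58 0.66
entorhinal temporal 1 2 1900 -0.70 0.50 0.72
frontalpole frontal 1 2 900 -1.35 0.55 0.75
fusiform temporal 1 2 9500 -0.92 0.78 0.54
inferiorparietal parietal 2 1 13000 -1.00 0.85 0.38
inferiortemporal temporal 1 2 10500 -0.95 0.80 0.56
insula insula 1 2 6600 -0.55 0.88 0.35
isthmuscingulate cingulate 2 2 2500 -0.60 0.64 0.46
lateraloccipital occipital 2 1 11500 -1.05 0.72 0.58
lateralorbitofrontal frontal 1 2 7500 -0.95 0.78 0.62
lingual occipital 2 2 7000 -0.80 0.68 0.62
medialorbitofrontal frontal 1 2 5500 -0.90 0.76 0.60
middletemporal temporal 1 2 10500 -0.95 0.86 0.46
paracentral frontal 1 1 3500 -0.65 0.62 0.42
parahippocampal temporal 1 2 2100 -0.68 0.48 0.68
parsopercularis frontal 1 1 4500 -1.00 0.70 0.44
parsorbitalis frontal 1 2 2100 -1.05 0.56 0.66
parstriangularis frontal 1 2 3900 -1.05 0.74 0.52
pericalcarine occipital 2 2 2100 -0.75 0.36 0.70
postcentral parietal 2 1 10000 -0.60 0.60 0.44
posteriorcingulate cingulate 2 1 3100 -0.62 0.76 0.34
precentral frontal 1 1 13500 -0.65 0.66 0.38
precuneus parietal 2 1 9800 -1.00 0.82 0.48
rostralanteriorcingulate cingulate 1 2 2500 -0.60 0.66 0.58
rostralmiddlefrontal frontal 1 1 16000 -1.10 0.82 0.58
superiorfrontal frontal 1 1 21500 -0.95 0.88 0.36
superiorparietal parietal 2 1 13500 -1.00 0.62 0.54
superiortemporal temporal 1 1 11500 -0.90 0.84 0.48
supramarginal parietal 2 1 10500 -1.00 0.80 0.40
temporalpole temporal 1 2 2400 -1.30 0.52 0.80
transversetemporal temporal 1 1 1100 -0.85 0.58 0.55
")
  # rescale volumes so total bilateral cortex (2 hemispheres) = 398,508 mm^3
  x$volume <- x$volume * (398508 / 2) / sum(x$volume)
  x
}

#' Adjacency between Desikan-Killiany parcels
#'
#' Edge list of boundary-sharing parcel pairs within a hemisphere, used to
#' place residual correlations between the slopes of spatially contiguous
#' ROIs in the confirmatory bifactor model. The list is a curated
#' approximation of which parcels share a border on the cortical surface;
#' users can supply their own two-column edge list anywhere an adjacency is
#' accepted.
#'
#' @return A two-column data.frame (\code{a}, \code{b}) of ROI name pairs.
#' @export
#' @examples
#' nrow(dk_adjacency())
dk_adjacency <- function() {
  txt <- "
bankssts superiortemporal
bankssts middletemporal
bankssts supramarginal
caudalanteriorcingulate rostralanteriorcingulate
caudalanteriorcingulate posteriorcingulate
caudalanteriorcingulate superiorfrontal
caudalmiddlefrontal rostralmiddlefrontal
caudalmiddlefrontal precentral
caudalmiddlefrontal superiorfrontal
caudalmiddlefrontal parsopercularis
cuneus pericalcarine
cuneus lateraloccipital
cuneus precuneus
cuneus lingual
entorhinal parahippocampal
entorhinal temporalpole
entorhinal fusiform
entorhinal inferiortemporal
frontalpole rostralmiddlefrontal
frontalpole medialorbitofrontal
frontalpole lateralorbitofrontal
frontalpole superiorfrontal
fusiform inferiortemporal
fusiform parahippocampal
fusiform lingual
fusiform lateraloccipital
inferiorparietal lateraloccipital
inferiorparietal supramarginal
inferiorparietal superiorparietal
inferiorparietal bankssts
inferiortemporal middletemporal
inferiortemporal lateraloccipital
insula superiortemporal
insula supramarginal
insula parsopercularis
insula lateralorbitofrontal
insula transversetemporal
insula precentral
insula postcentral
isthmuscingulate posteriorcingulate
isthmuscingulate precuneus
isthmuscingulate lingual
isthmuscingulate parahippocampal
lateraloccipital lingual
lateraloccipital pericalcarine
lateralorbitofrontal medialorbitofrontal
lateralorbitofrontal parsorbitalis
lateralorbitofrontal rostralmiddlefrontal
lingual pericalcarine
lingual parahippocampal
medialorbitofrontal rostralanteriorcingulate
medialorbitofrontal superiorfrontal
middletemporal superiortemporal
paracentral posteriorcingulate
paracentral precentral
paracentral postcentral
paracentral superiorfrontal
paracentral precuneus
parsopercularis parstriangularis
parsopercularis precentral
parsorbitalis parstriangularis
parsorbitalis rostralmiddlefrontal
parstriangularis rostralmiddlefrontal
postcentral precentral
postcentral supramarginal
postcentral superiorparietal
posteriorcingulate precuneus
posteriorcingulate superiorfrontal
precentral superiorfrontal
precuneus superiorparietal
rostralanteriorcingulate superiorfrontal
rostralmiddlefrontal superiorfrontal
superiorparietal supramarginal
superiortemporal supramarginal
superiortemporal transversetemporal
superiortemporal temporalpole
temporalpole middletemporal
"
  x <- utils::read.table(text = txt, col.names = c("a", "b"), stringsAsFactors = FALSE)
  rois <- dk_rois()$name
  stopifnot(all(x$a %in% rois), all(x$b %in% rois))
  x
}
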