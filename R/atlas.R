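#' Region atlas for regional morphometry
#'
#' An atlas is a data frame with one row per region and columns
#' `region_id`, `structure_class` (`"cortical_thickness"` or
#' `"subcortical_volume"`), `hemisphere` (`"left"`, `"right"`, `"midline"`)
#' and centroid coordinates `x`, `y`, `z` in millimetres. The default
#' parcellation has 68 cortical regions (34 per hemisphere, Desikan-
#' Killiany-style) whose thickness is analysed, and 14 subcortical
#' structures (7 per hemisphere) whose volume is analysed — 82 regions in
#' total.
#'
#' @param region_id character vector of unique region labels.
#' @param structure_class character vector, one of `"cortical_thickness"`,
#'   `"subcortical_volume"` per region.
#' @param hemisphere character vector, `"left"`, `"right"` or `"midline"`.
#' @param centroid numeric matrix (regions x 3) of centroid coordinates, mm.
#' @return A `region_atlas` data frame.
#' @export
region_atlas <- function(region_id, structure_class, hemisphere, centroid) {
  centroid <- as.matrix(centroid)
  stopifnot(length(region_id) == length(structure_class),
            length(region_id) == length(hemisphere),
            nrow(centroid) == length(region_id), ncol(centroid) == 3)
  if (anyDuplicated(region_id))
    stop("region_id values must be unique", call. = FALSE)
  if (!all(structure_class %in% c("cortical_thickness", "subcortical_volume")))
    stop("invalid structure_class", call. = FALSE)
  if (!all(hemisphere %in% c("left", "right", "midline")))
    stop("invalid hemisphere", call. = FALSE)
  if (!all(is.finite(centroid)))
    stop("centroids must be finite", call. = FALSE)
  out <- data.frame(region_id = as.character(region_id),
                    structure_class = structure_class,
                    hemisphere = hemisphere,
                    x = centroid[, 1], y = centroid[, 2], z = centroid[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("region_atlas", "data.frame")
  out
}

# Desikan-Killiany cortical parcel names (34 per hemisphere) and the seven
# subcortical structures with volumes that are stable across processing.
.dk_cortical <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula")

.subcortical <- c("thalamus", "caudate", "putamen", "pallidum",
                  "hippocampus", "amygdala", "accumbens")

#' Build the default 82-region synthetic atlas
#'
#' Places the 34 cortical parcels of each hemisphere on mirrored ellipsoid
#' shells (semi-axes 65 x 85 x 60 mm) and the 7 subcortical structures at
#' mirrored interior positions, so that left/right homologues have
#' centroids equal up to an x-sign flip. Deterministic given `seed`.
#'
#' @param seed integer seed controlling the (fixed) jitter of centroid
#'   placement.
#' @return A [region_atlas()] with 68 cortical-thickness and 14
#'   subcortical-volume regions.
#' @export
make_atlas <- function(seed = 0L) {
  with_seed(seed, {
    n_ct <- length(.dk_cortical)
    # quasi-uniform angular placement on the right-hemisphere half shell
    gold <- (1 + sqrt(5)) / 2
    i <- seq_len(n_ct)
    theta <- acos(1 - 2 * (i - 0.5) / n_ct)        # polar angle
    phi <- (2 * pi * i / gold) %% pi - pi / 2       # restricted to x > 0 side
    r_x <- 65; r_y <- 85; r_z <- 60
    x <- r_x * sin(theta) * cos(phi)
    y <- r_y * sin(theta) * sin(phi)
    z <- r_z * cos(theta)
    x <- abs(x) + 5                                 # keep off the midline
    jit <- matrix(stats::runif(n_ct * 3, -3, 3), n_ct, 3)
    ct_right <- cbind(x, y, z) + jit
    # deep-grey structures: interior, |x| in 8..30 mm
    sv_right <- cbind(
      x = c(12, 14, 24, 20, 26, 24, 9),
      y = c(-18, 10, 2, 0, -22, -4, 10),
      z = c(8, 12, 2, 0, -12, -16, -8)) +
      matrix(stats::runif(length(.subcortical) * 3, -1.5, 1.5),
             length(.subcortical), 3)
    mirror <- function(m) { m[, 1] <- -m[, 1]; m }
    region_atlas(
      region_id = c(paste0("L_", .dk_cortical), paste0("R_", .dk_cortical),
                    paste0("L_", .subcortical), paste0("R_", .subcortical)),
      structure_class = rep(c("cortical_thickness", "subcortical_volume"),
                            c(2 * n_ct, 2 * length(.subcortical))),
      hemisphere = c(rep(c("left", "right"), each = n_ct),
                     rep(c("left", "right"), each = length(.subcortical))),
      centroid = rbind(mirror(ct_right), ct_right,
                       mirror(sv_right), sv_right))
  })
}

#' Region names of a given structure class
#' @param atlas a [region_atlas()].
#' @param class `"cortical_thickness"` or `"subcortical_volume"`.
#' @return character vector of region ids.
#' @export
atlas_regions <- function(atlas,
                          class = c("cortical_thickness",
                                    "subcortical_volume")) {
  class <- match.arg(class)
  atlas$region_id[atlas$structure_class == class]
}

#' Pairwise Euclidean distances between region centroids
#' @param atlas a [region_atlas()].
#' @return symmetric matrix (regions x regions), millimetres, zero diagonal,
#'   dimnames set to region ids.
#' @export
region_distances <- function(atlas) {
  d <- as.matrix(stats::dist(as.matrix(atlas[, c("x", "y", "z")])))
  dimnames(d) <- list(atlas$region_id, atlas$region_id)
  d
}

#' Write / read an atlas as JSON
#' @param atlas a [region_atlas()].
#' @param path file path.
#' @return `read_atlas` returns a [region_atlas()]; `write_atlas` returns
#'   `path` invisibly.
#' @export
write_atlas <- function(atlas, path) {
  recs <- lapply(seq_len(nrow(atlas)), function(i) list(
    region_id = atlas$region_id[i],
    class = atlas$structure_class[i],
    hemisphere = atlas$hemisphere[i],
    centroid = c(atlas$x[i], atlas$y[i], atlas$z[i])))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  region_atlas(
    region_id = vapply(recs, `[[`, "", "region_id"),
    structure_class = vapply(recs, `[[`, "", "class"),
    hemisphere = vapply(recs, `[[`, "", "hemisphere"),
    centroid = t(vapply(recs, function(r) unlist(r$centroid), numeric(3))))
}
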