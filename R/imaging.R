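#' Project a z-stack to a 2-D multi-channel image
#'
#' Channel-wise sum or maximum across z planes. Sum projection is the one
#' used for redox and lipofuscin quantification; max projection is exposed
#' for uptake-style intensity readouts.
#'
#' @param stack An `image_stack` ([render_multichannel_stack()]) or a bare
#'   4-D array (y, x, channel, z).
#' @param mode `"sum"` or `"max"`.
#' @return A `projected_image`: array `data` (y, x, channel), channel names,
#'   pixel pitch.
#' @export
z_project <- function(stack, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  if (inherits(stack, "image_stack")) {
    arr <- stack$data; channels <- stack$channels; pitch <- stack$pixel_pitch_um
  } else {
    arr <- stack; channels <- NULL; pitch <- NA_real_
  }
  if (length(dim(arr)) != 4) stop("expected a (y, x, channel, z) array", call. = FALSE)
  if (dim(arr)[4] < 1) stop("need at least one z-plane", call. = FALSE)
  d <- dim(arr)
  flat <- matrix(arr, nrow = d[1] * d[2] * d[3], ncol = d[4])
  proj <- if (mode == "sum") rowSums(flat) else
    do.call(pmax, lapply(seq_len(d[4]), function(z) flat[, z]))
  proj <- array(proj, dim = d[1:3])
  structure(list(data = proj, channels = channels, pixel_pitch_um = pitch,
                 mode = mode), class = "projected_image")
}

proj_channel <- function(proj, name) {
  if (is.null(proj$channels) || !(name %in% proj$channels))
    stop(sprintf("channel '%s' not present", name), call. = FALSE)
  proj$data[, , match(name, proj$channels)]
}

otsu_threshold <- function(x) {
  rng <- range(x)
  EBImage::otsu(EBImage::Image((x - rng[1]) / diff(rng)), range = c(0, 1)) *
    diff(rng) + rng[1]
}

# Deterministic 2-means (Jenks-style) break. Otsu weights classes by their
# pixel counts and collapses when bright objects cover well under 1% of the
# field, as sparse macrophages do; the 2-means boundary stays between the
# background and object intensity modes regardless of class imbalance.
kmeans2_threshold <- function(x) {
  km <- stats::kmeans(as.vector(x), centers = range(x), iter.max = 50)
  mean(km$centers)
}

auto_threshold <- function(x, method = c("kmeans", "otsu")) {
  method <- match.arg(method)
  lx <- log1p(x)
  if (stats::sd(lx) == 0) return(NA_real_)
  expm1(if (method == "otsu") otsu_threshold(lx) else kmeans2_threshold(lx))
}

label_components <- function(mask, min_area) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  if (max(lab) > 0 && min_area > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(areas >= min_area)
    lab <- matrix(match(lab, keep, nomatch = 0L), nrow(lab), ncol(lab))
  }
  storage.mode(lab) <- "integer"
  lab
}

#' Segment macrophages from the lipofuscin channel
#'
#' Macrophages are the only cells with bright 1040-nm-excited lipofuscin-like
#' red autofluorescence, so they are segmented as connected components of
#' above-threshold lipofuscin pixels passing an area filter. The default
#' threshold is Otsu's method on the log-transformed channel, robust to
#' absolute brightness scale.
#'
#' @param proj A `projected_image` (sum projection).
#' @param threshold Intensity threshold on the raw channel; `NULL` for an
#'   automatic threshold on `log1p` intensities.
#' @param min_area Minimum component area in pixels.
#' @param method Automatic threshold method: `"kmeans"` (2-means break,
#'   robust to sparse bright objects) or `"otsu"`.
#' @return A `segmentation_labels` list: integer `labels` matrix (positive
#'   labels), the `threshold` used, `min_area`, and per-label `areas`.
#' @export
segment_macrophages <- function(proj, threshold = NULL, min_area = 20,
                                method = "kmeans") {
  x <- proj_channel(proj, "lipofuscin")
  if (all(x == 0)) {
    lab <- matrix(0L, nrow(x), ncol(x))
    return(list(labels = lab, threshold = NA_real_, min_area = min_area,
                areas = integer(0)))
  }
  if (is.null(threshold)) {
    threshold <- auto_threshold(x, method)
    if (is.na(threshold))
      stop("degenerate input: lipofuscin channel has zero variance",
           call. = FALSE)
  }
  lab <- label_components(x > threshold, min_area)
  areas <- if (max(lab) > 0) tabulate(lab[lab > 0], nbins = max(lab)) else integer(0)
  list(labels = lab, threshold = threshold, min_area = min_area, areas = areas)
}

#' Segment adipocyte cytoplasm rims
#'
#' Adipocytes appear as dark lipid voids surrounded by thin bright rims of
#' NAD(P)H + FAD autofluorescence. Rims are segmented by thresholding the
#' summed NAD(P)H + FAD image (Otsu on log intensities by default) after
#' removing macrophage pixels; any pixel claimed by both masks goes to the
#' macrophage (lipofuscin is the specific marker).
#'
#' @param proj A `projected_image`.
#' @param macro_labels Integer macrophage label matrix (from
#'   [segment_macrophages()]) or `NULL`.
#' @param threshold Intensity threshold; `NULL` for an automatic threshold
#'   on `log1p` intensities.
#' @param min_area Minimum rim area in pixels.
#' @param method Automatic threshold method as in [segment_macrophages()].
#' @return Same structure as [segment_macrophages()]; labels disjoint from
#'   the macrophage labels. Warns (and returns empty labels) when nothing is
#'   found.
#' @export
segment_adipocyte_cytoplasm <- function(proj, macro_labels = NULL,
                                        threshold = NULL, min_area = 50,
                                        method = "kmeans") {
  s <- proj_channel(proj, "nadh") + proj_channel(proj, "fad")
  if (is.null(threshold)) {
    threshold <- auto_threshold(s, method)
    if (is.na(threshold))
      stop("degenerate input: nadh+fad image has zero variance", call. = FALSE)
  }
  mask <- s > threshold
  if (!is.null(macro_labels)) mask[macro_labels > 0L] <- FALSE
  lab <- label_components(mask, min_area)
  if (max(lab) == 0)
    warning("no adipocyte cytoplasm rims found", call. = FALSE)
  areas <- if (max(lab) > 0) tabulate(lab[lab > 0], nbins = max(lab)) else integer(0)
  list(labels = lab, threshold = threshold, min_area = min_area, areas = areas)
}

label_centroids <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0)
    return(data.frame(id = integer(0), cy = numeric(0), cx = numeric(0),
                      area = integer(0)))
  idx <- which(labels > 0L, arr.ind = TRUE)
  v <- labels[labels > 0L]
  data.frame(id = ids,
             cy = tapply(idx[, 1], v, mean)[as.character(ids)],
             cx = tapply(idx[, 2], v, mean)[as.character(ids)],
             area = as.integer(table(v)[as.character(ids)]),
             row.names = NULL)
}

#' Detect crown-like structures among segmented macrophages
#'
#' Macrophage centroids are clustered by single linkage; any cluster of at
#' least `min_cls_cells` macrophages whose members chain within the linking
#' distance is called one crown-like structure (CLS). The default linking
#' distance is twice the median macrophage equivalent diameter.
#'
#' @param macro_labels Integer macrophage label matrix.
#' @param min_cls_cells Minimum macrophages per CLS (default 5).
#' @param link_dist Linking distance in pixels; `NULL` for the default.
#' @return A list: `n_cls`, `cls_id` (named per macrophage label, 0 = none),
#'   `link_dist`, `min_cls_cells`.
#' @export
detect_cls <- function(macro_labels, min_cls_cells = 5, link_dist = NULL) {
  cen <- label_centroids(macro_labels)
  if (nrow(cen) == 0)
    return(list(n_cls = 0L, cls_id = integer(0), link_dist = link_dist,
                min_cls_cells = min_cls_cells))
  if (is.null(link_dist))
    link_dist <- 2 * stats::median(2 * sqrt(cen$area / pi))
  cls_id <- rep(0L, nrow(cen))
  if (nrow(cen) > 1) {
    hc <- stats::hclust(stats::dist(cen[, c("cy", "cx")]), method = "single")
    grp <- stats::cutree(hc, h = link_dist)
    sizes <- table(grp)
    big <- as.integer(names(sizes)[sizes >= min_cls_cells])
    if (length(big) > 0)
      cls_id <- ifelse(grp %in% big, match(grp, big), 0L)
  }
  names(cls_id) <- cen$id
  list(n_cls = length(unique(cls_id[cls_id > 0])), cls_id = cls_id,
       link_dist = link_dist, min_cls_cells = min_cls_cells)
}

#' Optical redox ratio
#'
#' `I_FAD / (I_NAD(P)H + I_FAD)`; lower values indicate reduced oxidative
#' metabolism. Vectorized.
#'
#' @param i_fad,i_nadh Non-negative channel intensities (counts).
#' @return Ratio in \[0, 1\].
#' @export
redox_ratio <- function(i_fad, i_nadh) {
  if (any(i_fad < 0) || any(i_nadh < 0))
    stop("intensities must be non-negative", call. = FALSE)
  if (any(i_fad + i_nadh == 0))
    stop("redox ratio undefined: both intensities are zero", call. = FALSE)
  i_fad / (i_nadh + i_fad)
}

#' Extract per-cell records from a projected image and segmentation
#'
#' One record per label with mean channel intensities over the label's
#' pixels, the cell redox ratio, and CLS membership for macrophages.
#'
#' @param proj A `projected_image`.
#' @param macro_labels,adipo_labels Integer label matrices (either may be
#'   `NULL` or empty).
#' @param cls `NULL` or a [detect_cls()] result for the macrophage labels.
#' @return A data.frame of cell records: `cell_id`, `type`, `cls_member`,
#'   `area`, `mean_nadh`, `mean_fad`, `mean_lipofuscin`, `redox_ratio`,
#'   `cy`, `cx`.
#' @export
extract_cell_records <- function(proj, macro_labels = NULL,
                                 adipo_labels = NULL, cls = NULL) {
  chans <- lapply(c("nadh", "fad", "lipofuscin"), function(ch)
    proj_channel(proj, ch))
  one_type <- function(labels, type) {
    if (is.null(labels) || max(labels) == 0) return(NULL)
    cen <- label_centroids(labels)
    v <- labels[labels > 0L]
    key <- as.character(cen$id)
    means <- lapply(chans, function(m)
      as.numeric(tapply(m[labels > 0L], v, mean)[key]))
    cls_member <- rep(FALSE, nrow(cen))
    if (type == "macrophage" && !is.null(cls) && length(cls$cls_id) > 0)
      cls_member <- cls$cls_id[key] > 0
    data.frame(cell_id = cen$id, type = type, cls_member = cls_member,
               area = cen$area, mean_nadh = means[[1]], mean_fad = means[[2]],
               mean_lipofuscin = means[[3]],
               redox_ratio = redox_ratio(means[[2]], means[[1]]),
               cy = cen$cy, cx = cen$cx, stringsAsFactors = FALSE)
  }
  out <- rbind(one_type(macro_labels, "macrophage"),
               one_type(adipo_labels, "adipocyte"))
  if (is.null(out))
    out <- data.frame(cell_id = integer(0), type = character(0),
                      cls_member = logical(0), area = integer(0),
                      mean_nadh = numeric(0), mean_fad = numeric(0),
                      mean_lipofuscin = numeric(0), redox_ratio = numeric(0),
                      cy = numeric(0), cx = numeric(0))
  rownames(out) <- NULL
  out
}

#' Relative lipofuscin intensity
#'
#' Per-cell mean lipofuscin intensity divided by a normalizer, typically the
#' field mean of control-designated macrophages or an explicit constant.
#' Scale-invariant: doubling all intensities and the normalizer leaves the
#' ratios unchanged.
#'
#' @param records A cell-record data.frame ([extract_cell_records()]).
#' @param normalizer Positive scalar.
#' @return `records` with a `lipofuscin_rel` column added.
#' @export
relative_lipofuscin_intensity <- function(records, normalizer) {
  stop_if_not_scalar_number(normalizer, "normalizer")
  if (normalizer <= 0) stop("normalizer must be > 0", call. = FALSE)
  records$lipofuscin_rel <- records$mean_lipofuscin / normalizer
  records
}

#' Aggregate cell records into per-field data points
#'
#' One data point per cell type and field: the mean of each metric over up to
#' `cells_per_point` cells (the convention of averaging 10 cells per field of
#' view). Fields with fewer cells use all available and are flagged.
#'
#' @param records Cell records, optionally with a `lipofuscin_rel` column.
#' @param cells_per_point Cells averaged per data point (default 10).
#' @return A data.frame with one row per cell type: metric means, `n_cells`,
#'   `short_count` flag.
#' @export
fov_aggregate <- function(records, cells_per_point = 10) {
  if (nrow(records) == 0) stop("no cell records to aggregate", call. = FALSE)
  metrics <- intersect(c("redox_ratio", "a1", "t1", "t2", "mean_nadh",
                         "mean_fad", "mean_lipofuscin", "lipofuscin_rel"),
                       names(records))
  out <- lapply(split(records, records$type), function(df) {
    use <- df[seq_len(min(nrow(df), cells_per_point)), , drop = FALSE]
    row <- as.data.frame(lapply(use[metrics], mean, na.rm = TRUE))
    row$type <- df$type[1]
    row$n_cells <- nrow(use)
    row$short_count <- nrow(df) < cells_per_point
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
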