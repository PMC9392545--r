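#' Find the peak vertex of a statistic map within a mask
#'
#' The functional peak is the vertex maximizing the statistic inside the
#' mask; ties break toward the lowest vertex index.
#'
#' @param statmap Numeric per-vertex statistic vector.
#' @param mask Integer vector of candidate 1-based vertex indices.
#' @return List with `vertex` (index) and `value` (statistic there).
#' @export
find_peak <- function(statmap, mask) {
  if (length(mask) == 0) stop("empty mask", call. = FALSE)
  vals <- statmap[mask]
  if (all(is.na(vals))) stop("statistic is all NA within the mask", call. = FALSE)
  mask <- sort(mask)
  vals <- statmap[mask]
  i <- which(vals == max(vals, na.rm = TRUE))[1]
  list(vertex = mask[i], value = vals[i])
}

#' Build equally spaced line ROIs between two functional peaks
#'
#' Places coordinates along the straight 3-D segment connecting the two peak
#' vertices: `n_between` interior coordinates at equal spacing, the two
#' peaks themselves, and `n_extend` linearly extrapolated coordinates beyond
#' each end at the same spacing. Each coordinate is grouped with its `k`
#' Euclidean-nearest mesh vertices to form one ROI. With the defaults this
#' yields 51 ROIs with the peaks at 1-based indices 16 and 36.
#'
#' Adjacent ROIs may share vertices when the spacing is finer than the mesh
#' resolution; the overlap fraction is recorded in the result.
#'
#' @param mesh A `surface_mesh`.
#' @param peak_a,peak_b Distinct 1-based vertex indices (e.g. the FFA and
#'   PPA peak foci).
#' @param n_between Interior coordinates between the peaks (default 19).
#' @param n_extend Extrapolated coordinates beyond each peak (default 15).
#' @param k Vertices per ROI (default 5).
#' @return A `roi_line`: list with `rois` (list of length-`k` integer
#'   vectors, ordered along the line), `coords` (ROI coordinates, mm),
#'   `anchor_a`, `anchor_b` (1-based ROI indices of the peaks), `spacing`
#'   (mm) and `overlap_fraction`.
#' @examples
#' mesh <- build_sphere_patch_mesh(2, 40)
#' line <- build_line_rois(mesh, 1, 80)
#' length(line$rois)  # 51
#' line$anchor_a      # 16
#' @export
build_line_rois <- function(mesh, peak_a, peak_b, n_between = 19,
                            n_extend = 15, k = 5) {
  if (peak_a == peak_b) stop("peaks must be distinct", call. = FALSE)
  if (n_vertices(mesh) < k) stop("mesh has fewer than `k` vertices", call. = FALSE)
  a <- mesh$vertices[peak_a, ]
  b <- mesh$vertices[peak_b, ]
  step <- (b - a) / (n_between + 1)
  # positions: -n_extend .. 0 (peak a) .. n_between+1 (peak b) .. +n_extend
  t_idx <- seq.int(-n_extend, n_between + 1 + n_extend)
  coords <- outer(t_idx, step) + rep(a, each = length(t_idx))
  rois <- lapply(seq_len(nrow(coords)), function(i) {
    d2 <- colSums((t(mesh$vertices) - coords[i, ])^2)
    order(d2)[seq_len(k)]
  })
  n_roi <- length(rois)
  shared <- vapply(seq_len(n_roi - 1L), function(i) {
    length(intersect(rois[[i]], rois[[i + 1L]]))
  }, integer(1))
  structure(
    list(rois = rois, coords = coords,
         anchor_a = n_extend + 1L,
         anchor_b = n_extend + n_between + 2L,
         spacing = sqrt(sum(step^2)),
         k = k,
         overlap_fraction = mean(shared) / k),
    class = "roi_line"
  )
}

#' @export
print.roi_line <- function(x, ...) {
  cat("<roi_line> ", length(x$rois), " ROIs of ", x$k,
      " vertices, anchors at ", x$anchor_a, " and ", x$anchor_b,
      ", spacing ", signif(x$spacing, 4), " mm\n", sep = "")
  invisible(x)
}

#' Build the two occipital-pole lines
#'
#' Two virtual lines sharing a start coordinate (the occipital pole) and
#' running to the face-patch and house-patch peaks respectively. With the
#' defaults each line has 60 ROIs, the pole at 1-based index 16 and the
#' patch peak at index 45.
#'
#' @param mesh A `surface_mesh`.
#' @param occipital_vertex Shared start vertex.
#' @param peak_ffa,peak_ppa End peak vertices.
#' @param n_between,n_extend,k As in [build_line_rois()] (defaults 28, 15, 5).
#' @return List with elements `to_ffa` and `to_ppa`, each a `roi_line`.
#' @export
build_occipital_lines <- function(mesh, occipital_vertex, peak_ffa, peak_ppa,
                                  n_between = 28, n_extend = 15, k = 5) {
  list(
    to_ffa = build_line_rois(mesh, occipital_vertex, peak_ffa,
                             n_between = n_between, n_extend = n_extend, k = k),
    to_ppa = build_line_rois(mesh, occipital_vertex, peak_ppa,
                             n_between = n_between, n_extend = n_extend, k = k)
  )
}

#' Serialize line ROIs to JSON
#'
#' Vertex indices are written 0-based (the on-disk convention for surface
#' data interchange) and restored to 1-based on read.
#'
#' @param line A `roi_line`.
#' @param path Output path.
#' @return `path` invisibly; `read_roi_line_json` returns a `roi_line`.
#' @export
write_roi_line_json <- function(line, path) {
  jsonlite::write_json(
    list(rois = lapply(line$rois, function(v) v - 1L),
         anchor_a = line$anchor_a, anchor_b = line$anchor_b,
         spacing = line$spacing, k = line$k,
         coords = unname(as.data.frame(line$coords))),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_roi_line_json
#' @export
read_roi_line_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(rois = lapply(seq_len(nrow(j$rois)), function(i) as.integer(j$rois[i, ]) + 1L),
         coords = as.matrix(as.data.frame(j$coords)),
         anchor_a = j$anchor_a, anchor_b = j$anchor_b,
         spacing = j$spacing, k = j$k,
         overlap_fraction = NA_real_),
    class = "roi_line"
  )
}
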