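#' @include io.R
NULL

# Lesion-level substrate: connected-component decomposition, overlap
# matching of predictions against ground truth, category/aetiology
# assignment for predicted components, and axial diameter measurement.
# Every delineated component is a distinct lesion irrespective of size:
# no minimum-size filter is applied anywhere.

emptyLesionTable <- function() {
  data.frame(lesion_id = character(), source = character(),
             voxel_count = integer(), volume_mL = numeric(),
             diameter_mm = numeric(), category = character(),
             station_or_organ = character(), invasion = character(),
             etiology_class = character(), etiology = character(),
             annotated = logical(), stringsAsFactors = FALSE)
}

#' Decompose a label volume into lesions
#'
#' Connected components are computed per positive label value under the
#' chosen 3D adjacency, so instance masks keep touching instances apart
#' while binary prediction masks decompose into components. Lesions are
#' ordered (and for binary masks, numbered) by the scan-order position
#' of their first voxel, which makes the decomposition deterministic.
#' For instance masks whose labels each form a single component, the
#' instance value is kept as the lesion id.
#'
#' @param vol a [LabelVolume-class].
#' @param connectivity 6, 18 or 26 (default 26, full 3D adjacency).
#' @param source lesion provenance tag, `"ground_truth"` or `"predicted"`.
#' @return a [LesionSet-class]; empty mask gives an empty set.
#' @examples
#' a <- array(0L, c(4, 4, 4)); a[1, 1, 1] <- 1L; a[2, 2, 2] <- 1L
#' v <- LabelVolume(a)
#' nLesions(extractComponents(v, 26))  # corner contact: one component
#' nLesions(extractComponents(v, 6))   # faces only: two
#' @export
extractComponents <- function(vol, connectivity = 26L,
                              source = c("ground_truth", "predicted")) {
  stopifnot(is(vol, "LabelVolume"))
  source <- match.arg(source)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  arr <- vol@voxels
  d <- dim(arr)
  lab <- cc_label3d(as.integer(arr), as.integer(d), connectivity)
  k <- max(lab, 0L)
  if (k == 0L)
    return(new("LesionSet", table = emptyLesionTable(), voxelIndex = list(),
               dim = as.integer(d), spacing = vol@spacing))
  idx <- split(seq_along(lab)[lab > 0L], lab[lab > 0L])
  idx <- idx[order(as.integer(names(idx)))]
  # keep instance values as ids when each instance is one component
  instVal <- vapply(idx, function(v) arr[v[1]], integer(1))
  ids <- if (all(instVal == 1L)) {
    as.character(seq_len(k))
  } else if (!anyDuplicated(instVal)) {
    as.character(instVal)
  } else {
    # an instance split into several components keeps a derived id
    sub <- stats::ave(seq_along(instVal), instVal, FUN = seq_along)
    cnt <- stats::ave(seq_along(instVal), instVal, FUN = length)
    ifelse(cnt == 1L, as.character(instVal), paste0(instVal, ".", sub))
  }
  counts <- lengths(idx)
  vvol <- voxelVolumeMm3(vol)
  tb <- data.frame(lesion_id = ids, source = source,
                   voxel_count = as.integer(counts),
                   volume_mL = counts * vvol / 1000,
                   diameter_mm = NA_real_, category = NA_character_,
                   station_or_organ = NA_character_, invasion = NA_character_,
                   etiology_class = NA_character_, etiology = NA_character_,
                   annotated = NA, stringsAsFactors = FALSE)
  names(idx) <- ids
  new("LesionSet", table = tb, voxelIndex = idx, dim = as.integer(d),
      spacing = vol@spacing)
}

#' Match predicted components to ground-truth lesions
#'
#' A predicted component is a true positive iff it shares at least
#' `minOverlapVoxels` voxels with at least one ground-truth lesion; a
#' ground-truth lesion is detected iff at least one predicted component
#' overlaps it. One predicted component overlapping several ground-truth
#' lesions is recorded as a merge event: it detects all of them but
#' counts once on the prediction side. With the default threshold of one
#' voxel this reproduces the zero-overlap definition behind false
#' negative / false positive volume. An optional IoU threshold can be
#' layered on top (off by default).
#'
#' @param gtSet,predSet [LesionSet-class]s from the same grid.
#' @param minOverlapVoxels minimum shared voxels for a match (default 1).
#' @param minIoU optional minimum intersection-over-union per pair
#'   (default 0 = disabled).
#' @return a [MatchResult-class].
#' @export
matchLesions <- function(gtSet, predSet, minOverlapVoxels = 1L, minIoU = 0) {
  stopifnot(is(gtSet, "LesionSet"), is(predSet, "LesionSet"))
  if (!identical(gtSet@dim, predSet@dim))
    stop("grid mismatch: lesion sets come from different grids")
  pairs <- data.frame(gt_id = character(), pred_id = character(),
                      overlap_voxels = integer(), stringsAsFactors = FALSE)
  if (nLesions(gtSet) && nLesions(predSet)) {
    gtOwner <- integer(prod(gtSet@dim))
    for (i in seq_along(gtSet@voxelIndex))
      gtOwner[gtSet@voxelIndex[[i]]] <- i
    res <- list()
    for (j in seq_along(predSet@voxelIndex)) {
      own <- gtOwner[predSet@voxelIndex[[j]]]
      own <- own[own > 0L]
      if (!length(own)) next
      tab <- table(own)
      keep <- as.integer(tab) >= minOverlapVoxels
      if (minIoU > 0 && any(keep)) {
        gi <- as.integer(names(tab))
        iou <- as.integer(tab) /
          (gtSet@table$voxel_count[gi] + predSet@table$voxel_count[j] - as.integer(tab))
        keep <- keep & iou >= minIoU
      }
      if (!any(keep)) next
      res[[length(res) + 1L]] <- data.frame(
        gt_id = gtSet@table$lesion_id[as.integer(names(tab))[keep]],
        pred_id = predSet@table$lesion_id[j],
        overlap_voxels = as.integer(tab)[keep], stringsAsFactors = FALSE)
    }
    if (length(res)) pairs <- do.call(rbind, res)
  }
  fn <- setdiff(gtSet@table$lesion_id, pairs$gt_id)
  fp <- setdiff(predSet@table$lesion_id, pairs$pred_id)
  merges <- data.frame(pred_id = character(), n_gt = integer(),
                       gt_ids = character(), stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    byPred <- split(pairs$gt_id, pairs$pred_id)
    multi <- byPred[lengths(byPred) > 1L]
    if (length(multi))
      merges <- data.frame(pred_id = names(multi),
                           n_gt = lengths(multi),
                           gt_ids = vapply(multi, paste, "", collapse = ";"),
                           stringsAsFactors = FALSE)
  }
  new("MatchResult", tpPairs = pairs, fnIds = fn, fpIds = fp,
      mergeEvents = merges)
}

#' Assign category, station and aetiology to predicted lesions
#'
#' Matched predicted components inherit category, station/organ and
#' invasion flags from the overlapped ground-truth lesion (largest
#' overlap wins for merged components). Unmatched (false-positive)
#' components take the compartment holding the majority of their voxels,
#' ties broken by the compartment of the centroid voxel; components
#' lying entirely outside all compartments default to category M — the
#' extrathoracic search space is where false positives concentrate.
#' Aetiology for false positives is taken from sidecar marker points
#' (a row whose `center_*_mm` point falls inside the component);
#' unannotated false positives are tagged `"benign"` with
#' `annotated = FALSE` rather than dropped.
#'
#' @param predSet predicted [LesionSet-class].
#' @param match [MatchResult-class] from [matchLesions()].
#' @param compartmentMap [LabelVolume-class] of compartment ids.
#' @param compartments data.frame mapping `compartment_id` to `category`
#'   and `label` (as in [PhantomSpec-class]).
#' @param gtSet ground-truth [LesionSet-class] with metadata filled.
#' @param sidecar optional validated sidecar data.frame.
#' @return `predSet` with annotation columns filled.
#' @export
assignCategory <- function(predSet, match, compartmentMap, compartments,
                           gtSet, sidecar = NULL) {
  stopifnot(is(predSet, "LesionSet"), is(match, "MatchResult"))
  tb <- predSet@table
  if (!nrow(tb)) return(predSet)
  gtTb <- gtSet@table
  cmap <- compartmentMap@voxels
  sp <- predSet@spacing
  for (j in seq_len(nrow(tb))) {
    pid <- tb$lesion_id[j]
    hits <- match@tpPairs[match@tpPairs$pred_id == pid, , drop = FALSE]
    if (nrow(hits)) {
      best <- hits$gt_id[which.max(hits$overlap_voxels)]
      g <- gtTb[gtTb$lesion_id == best, , drop = FALSE]
      tb$category[j] <- g$category[1]
      tb$station_or_organ[j] <- g$station_or_organ[1]
      tb$invasion[j] <- g$invasion[1]
      tb$etiology_class[j] <- "tumour"
      tb$annotated[j] <- TRUE
    } else {
      vox <- predSet@voxelIndex[[pid]]
      comp <- cmap[vox]
      comp <- comp[comp > 0L]
      cid <- NA_integer_
      if (length(comp)) {
        tab <- table(comp)
        top <- as.integer(names(tab)[tab == max(tab)])
        if (length(top) == 1L) cid <- top
        else {
          # tie: compartment of the centroid voxel (nearest foreground
          # compartment voxel of the component to its centroid)
          co <- arrayInd(vox, predSet@dim)
          cen <- colMeans(co)
          dd <- rowSums((t(t(co) - cen))^2)
          ordv <- vox[order(dd)]
          cc <- cmap[ordv]
          cc <- cc[cc > 0L & cc %in% top]
          cid <- if (length(cc)) cc[1] else top[1]
        }
      }
      if (is.na(cid)) {
        tb$category[j] <- "M"
        tb$station_or_organ[j] <- "extrathoracic_unspecified"
      } else {
        row <- compartments[compartments$compartment_id == cid, , drop = FALSE]
        tb$category[j] <- row$category[1]
        tb$station_or_organ[j] <- row$label[1]
      }
      # aetiology from sidecar marker points, if provided
      tb$etiology_class[j] <- "benign"
      tb$annotated[j] <- FALSE
      if (!is.null(sidecar) && nrow(sidecar)) {
        fpRows <- sidecar[!is.na(sidecar$center_x_mm) &
                          !is.na(sidecar$etiology_class) &
                          sidecar$etiology_class != "tumour", , drop = FALSE]
        if (nrow(fpRows)) {
          ivox <- floor(cbind(fpRows$center_x_mm / sp[1],
                              fpRows$center_y_mm / sp[2],
                              fpRows$center_z_mm / sp[3])) + 1L
          inside <- ivox[, 1] >= 1 & ivox[, 2] >= 1 & ivox[, 3] >= 1 &
            ivox[, 1] <= predSet@dim[1] & ivox[, 2] <= predSet@dim[2] &
            ivox[, 3] <= predSet@dim[3]
          if (any(inside)) {
            lin <- (ivox[inside, 3] - 1L) * predSet@dim[1] * predSet@dim[2] +
                   (ivox[inside, 2] - 1L) * predSet@dim[1] + ivox[inside, 1]
            hit <- which(lin %in% vox)
            if (length(hit)) {
              r <- fpRows[inside, , drop = FALSE][hit[1], ]
              tb$etiology_class[j] <- r$etiology_class
              tb$etiology[j] <- r$etiology
              tb$annotated[j] <- TRUE
            }
          }
        }
      }
    }
  }
  predSet@table <- tb
  predSet
}

#' Measure axial lesion diameters
#'
#' Clinical T-size is measured on axial sections, so the diameter is the
#' maximal in-plane extent over all axial (z) slices the lesion spans:
#' the largest pairwise distance between in-plane voxel centres plus one
#' in-plane voxel width (a single voxel therefore measures one voxel
#' width, and an n-voxel axial line n voxel widths).
#'
#' @param lesionSet a [LesionSet-class].
#' @return the set with `diameter_mm` filled in its table.
#' @export
measureDiameter <- function(lesionSet) {
  stopifnot(is(lesionSet, "LesionSet"))
  tb <- lesionSet@table
  if (!nrow(tb)) return(lesionSet)
  sp <- lesionSet@spacing
  w <- mean(sp[1:2])
  for (i in seq_len(nrow(tb))) {
    co <- arrayInd(lesionSet@voxelIndex[[ tb$lesion_id[i] ]], lesionSet@dim)
    dmax <- 0
    for (z in unique(co[, 3])) {
      pl <- co[co[, 3] == z, 1:2, drop = FALSE]
      xy <- cbind(pl[, 1] * sp[1], pl[, 2] * sp[2])
      if (nrow(xy) > 3) {
        h <- grDevices::chull(xy)
        xy <- xy[h, , drop = FALSE]
      }
      if (nrow(xy) > 1) {
        dz <- max(stats::dist(xy))
        if (dz > dmax) dmax <- dz
      }
    }
    tb$diameter_mm[i] <- dmax + w
  }
  lesionSet@table <- tb
  lesionSet
}
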