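# Skeleton extraction and conversion of voxel skeletons into polyline
# segments between tips and branch points. Used by both the 3D micro-CT
# tracer and the 2D angiogram branch counter (a 2D image is handled as a
# one-slice volume; 26/6-connectivity then degenerates to 8/4).

#' Topological curve thinning of a binary mask
#'
#' Reduces a 2D or 3D binary mask to a one-voxel-wide centerline skeleton by
#' iterative removal of simple border voxels (6-subiteration directional
#' thinning with the Malandain-Bertrand simple-point characterization),
#' preserving curve endpoints.
#'
#' @param mask logical matrix, 3D logical array, or [binary_volume()].
#' @return Skeleton of the same shape and type as the input mask.
#' @export
skeletonize <- function(mask) {
  if (inherits(mask, "binary_volume"))
    return(binary_volume(skeletonize(mask$mask), mask$voxel_size))
  if (is.matrix(mask)) {
    a <- array(mask, c(dim(mask), 1L))
    return(cpp_thin3d(a, dim(a))[, , 1])
  }
  cpp_thin3d(mask, dim(mask))
}

#' Label connected components (26-connectivity)
#'
#' @param mask logical matrix or 3D array.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask) {
  if (is.matrix(mask)) {
    a <- array(mask, c(dim(mask), 1L))
    return(cpp_label3d(a, dim(a))[, , 1])
  }
  cpp_label3d(mask, dim(mask))
}

# Drop connected components smaller than min_size voxels.
remove_small_components <- function(mask, min_size) {
  if (min_size <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  out <- array(lab %in% keep, dim(mask))
  if (is.matrix(mask)) out <- matrix(out, nrow(mask), ncol(mask))
  out
}

# Binary dilation by Euclidean radius, via the distance transform of the
# complement.
dilate_mask <- function(mask, radius) {
  if (radius <= 0 || !any(mask)) return(mask)
  a <- if (is.matrix(mask)) array(mask, c(dim(mask), 1L)) else mask
  d <- cpp_edt3d(!a, dim(a))
  out <- a | (d <= radius)
  if (is.matrix(mask)) out[, , 1] else out
}

# Euclidean distance transform (distance of foreground voxels to the
# nearest background voxel; the outside counts as background).
distance_transform <- function(mask) {
  a <- if (is.matrix(mask)) array(mask, c(dim(mask), 1L)) else mask
  d <- cpp_edt3d(a, dim(a))
  if (is.matrix(mask)) d[, , 1] else d
}

# Decompose a skeleton mask into polyline segments delimited by tips and
# branch points. Adjacent branch voxels are collapsed into one junction
# cluster; every skeleton edge path between two critical points becomes one
# segment. Returns list(segments = list(path, junc), n_junctions); `path`
# is an n x 3 matrix of voxel coordinates (junction voxels appended at
# attached ends), `junc` the two junction-cluster ids (NA for a free tip).
skeleton_segments <- function(skel, min_fragment = 0, prune_tips = 0,
                              merge_len = 4) {
  if (is.matrix(skel)) skel <- array(skel, c(dim(skel), 1L))
  res <- skeleton_segments_once(skel, min_fragment)
  if (prune_tips > 0 && length(res$segments)) {
    spur <- vapply(res$segments, function(s) {
      n_tip <- sum(is.na(s$junc))
      n_tip == 1 && nrow(s$path) < prune_tips
    }, logical(1))
    if (any(spur)) {
      for (s in res$segments[spur]) {
        p <- s$path
        # remove interior voxels only; junction voxels stay
        int <- p[!seq_len(nrow(p)) %in% attr(p, "junction_rows"), , drop = FALSE]
        skel[cbind(int[, 1], int[, 2], int[, 3])] <- FALSE
      }
      res <- skeleton_segments_once(skel, min_fragment)
    }
  }
  if (merge_len > 0) res <- contract_junction_links(res, merge_len)
  res
}

# Thinning occasionally splits one anatomical branch point into several
# nearby junction clusters linked by very short segments. Contract such
# links: merge the clusters (union-find) and drop the stub segments, so
# the branch graph has one junction per anatomical branch point.
contract_junction_links <- function(res, merge_len) {
  segs <- res$segments
  if (!length(segs) || res$n_junctions < 2) return(res)
  parent <- seq_len(res$n_junctions)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  short <- logical(length(segs))
  for (k in seq_along(segs)) {
    s <- segs[[k]]
    if (any(is.na(s$junc))) next
    if (polyline_length(s$path) >= merge_len) next
    short[k] <- TRUE
    ra <- find(s$junc[1]); rb <- find(s$junc[2])
    if (ra != rb) parent[ra] <- rb
  }
  if (!any(short)) return(res)
  segs <- segs[!short]
  for (k in seq_along(segs)) {
    j <- segs[[k]]$junc
    segs[[k]]$junc <- c(if (is.na(j[1])) NA_integer_ else find(j[1]),
                        if (is.na(j[2])) NA_integer_ else find(j[2]))
  }
  res$segments <- segs
  res
}

skeleton_segments_once <- function(skel, min_fragment) {
  dims <- dim(skel)
  skel <- remove_small_components(skel, max(2, min_fragment))
  lin <- which(skel)
  if (!length(lin))
    return(list(segments = list(), n_junctions = 0L, skeleton = skel))
  coords <- arrayInd(lin, dims)
  n <- length(lin)

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  ei <- ej <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[k, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nlin <- nb[ok, 1] + dims[1] * (nb[ok, 2] - 1) +
      dims[1] * dims[2] * (nb[ok, 3] - 1)
    j <- match(nlin, lin)
    hit <- !is.na(j)
    ei[[k]] <- which(ok)[hit]
    ej[[k]] <- j[hit]
  }
  ai <- unlist(ei)
  aj <- unlist(ej)
  deg <- tabulate(ai, nbins = n)  # each undirected edge appears twice in ai
  # adjacency list (C-level split)
  adj <- split(aj, factor(ai, levels = seq_len(n)))

  is_junc <- deg >= 3
  junc_cluster <- rep(0L, n)
  n_junc <- 0L
  if (any(is_junc)) {
    jmask <- array(FALSE, dims)
    jmask[lin[is_junc]] <- TRUE
    jlab <- cpp_label3d(jmask, dims)
    junc_cluster <- jlab[lin]
    n_junc <- max(junc_cluster)
  }

  segments <- list()
  add_seg <- function(path_rows, ja, jb, junction_rows = integer(0)) {
    p <- coords[path_rows, , drop = FALSE]
    attr(p, "junction_rows") <- junction_rows
    segments[[length(segments) + 1L]] <<- list(
      path = p, junc = c(if (ja > 0) ja else NA_integer_,
                         if (jb > 0) jb else NA_integer_))
  }

  # interior (non-junction) components are open paths or cycles
  if (any(!is_junc)) {
    imask <- array(FALSE, dims)
    imask[lin[!is_junc]] <- TRUE
    ilab_arr <- cpp_label3d(imask, dims)
    icomp <- ilab_arr[lin]             # 0 for junction voxels
    ideg <- vapply(seq_len(n), function(v) {
      if (icomp[v] == 0) 0L else sum(icomp[adj[[v]]] == icomp[v])
    }, integer(1))
    ncomp <- max(icomp)
    starts <- integer(ncomp)
    # prefer an endpoint of the interior path as the walk start
    for (v in order(ideg)) {
      c0 <- icomp[v]
      if (c0 > 0 && starts[c0] == 0L) starts[c0] <- v
    }
    for (c0 in seq_len(ncomp)) {
      v <- starts[c0]
      if (v == 0L) next
      path <- integer(0)
      prev <- -1L
      repeat {
        path <- c(path, v)
        nbrs <- adj[[v]]
        nbrs <- nbrs[icomp[nbrs] == c0 & nbrs != prev &
                       !(nbrs %in% path)]
        if (!length(nbrs)) break
        prev <- v
        v <- nbrs[1]
      }
      ends <- c(path[1], path[length(path)])
      jr <- integer(0)
      j1 <- adj[[ends[1]]]
      j1 <- j1[is_junc[j1]]
      ja <- 0L
      if (length(j1)) {
        path <- c(j1[1], path)
        ja <- junc_cluster[j1[1]]
        jr <- c(jr, 1L)
      }
      j2 <- adj[[ends[2]]]
      j2 <- j2[is_junc[j2]]
      if (length(j1)) j2 <- setdiff(j2, j1[1])
      jb <- 0L
      if (length(j2)) {
        path <- c(path, j2[1])
        jb <- junc_cluster[j2[1]]
        jr <- c(jr, length(path))
      }
      if (length(path) >= 2) add_seg(path, ja, jb, jr)
    }
  }

  # direct edges between distinct junction clusters
  if (n_junc >= 2) {
    jj <- is_junc[ai] & is_junc[aj] & ai < aj
    if (any(jj)) {
      ca <- junc_cluster[ai[jj]]
      cb <- junc_cluster[aj[jj]]
      cross <- which(ca != cb)
      if (length(cross)) {
        key <- paste(pmin(ca[cross], cb[cross]), pmax(ca[cross], cb[cross]))
        first <- cross[!duplicated(key)]
        ii <- ai[jj][first]; ji <- aj[jj][first]
        for (q in seq_along(first))
          add_seg(c(ii[q], ji[q]), junc_cluster[ii[q]], junc_cluster[ji[q]],
                  c(1L, 2L))
      }
    }
  }

  out_skel <- array(FALSE, dims)
  out_skel[lin] <- TRUE
  list(segments = segments, n_junctions = n_junc, skeleton = out_skel)
}

# Breadth-first depth of each segment from a root segment, where two
# segments are adjacent when they share a junction cluster. Segments in
# other connected components get NA.
segment_depths <- function(segments, root) {
  ns <- length(segments)
  depth <- rep(NA_integer_, ns)
  if (!ns) return(depth)
  juncs <- lapply(segments, function(s) s$junc[!is.na(s$junc)])
  depth[root] <- 1L
  frontier <- root
  while (length(frontier)) {
    nxt <- integer(0)
    for (f in frontier) {
      if (!length(juncs[[f]])) next
      for (s in seq_len(ns)) {
        if (!is.na(depth[s])) next
        if (length(intersect(juncs[[s]], juncs[[f]])))
          nxt <- c(nxt, s)
      }
      depth[nxt] <- depth[f] + 1L
      # consume shared junctions so depth spreads outward only
    }
    frontier <- unique(nxt)
  }
  depth
}
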