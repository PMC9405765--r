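# 26-connectivity is the single declared 3D connectivity for all region
# reasoning in this package.

#' Label connected components of a 3D binary mask (26-neighbourhood)
#'
#' Components are found on the voxel adjacency graph (igraph); labels are
#' renumbered so that label 1 is the component containing the lowest linear
#' voxel index, label 2 the next, and so on, which makes tie-breaking by
#' "lowest linear index" reproducible.
#'
#' @param mask logical 3D array.
#' @return integer array of the same shape; 0 = background.
#' @export
label_components <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  dm <- dim(mask)
  lab <- array(0L, dim = dm)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  idx_of <- integer(prod(dm)); idx_of[fg] <- seq_along(fg)
  coords <- arrayInd(fg, dm)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & (offs[, 1] > 0 |
           (offs[, 1] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 3] > 0)))), ,
           drop = FALSE]  # 13 forward offsets, each undirected edge once
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[r, ], nrow(coords), 3L, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dm[1] + (nb[ok, 3] - 1L) * dm[1] * dm[2]
    j <- idx_of[lin]
    keep <- j > 0L
    if (any(keep)) edges <- rbind(edges, cbind(which(ok)[keep], j[keep]))
  }
  g <- igraph::graph_from_edgelist(rbind(edges, cbind(seq_along(fg), seq_along(fg))),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(fg)]
  # renumber by first (lowest linear index) appearance
  first <- tapply(seq_along(fg), comp, min)
  order_lab <- rank(fg[first])
  names(order_lab) <- names(first)
  lab[fg] <- as.integer(order_lab[as.character(comp)])
  lab
}

#' Count lesion regions and extract the largest
#'
#' Connected components of the lesion mask under 26-connectivity. When
#' several separate lesion regions exist, only the largest (by voxel count;
#' ties broken by the region containing the lowest linear voxel index) is
#' retained for volumetric feature computation.
#'
#' @param mask logical 3D array (lesion mask).
#' @return list with `n_regions` and `largest` (logical mask, empty when
#'   the input is empty).
#' @export
count_regions <- function(mask) {
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) {
    return(list(n_regions = 0L, largest = array(FALSE, dim = dim(mask))))
  }
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  best <- which(sizes == max(sizes))[1L]  # labels already ordered by lowest index
  list(n_regions = as.integer(n), largest = lab == best)
}
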