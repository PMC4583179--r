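#' Label connected components of a binary mask
#'
#' Flood-fill labelling with 8- (default) or 4-connectivity. Written
#' in-package because the edge-map component counts of the evaluation
#' protocol are 8-connected.
#'
#' @param mask logical matrix or [EdgeMap-class].
#' @param connectivity 8 (queen) or 4 (rook).
#' @return integer matrix of the same shape; 0 = background, components are
#'   numbered 1..k in first-encounter (column-major) order.
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  if (is(mask, "EdgeMap")) mask <- mask@.Data
  stopifnot(is.logical(mask), is.matrix(mask))
  connectivity <- match.arg(as.character(connectivity), c("8", "4"))
  m <- nrow(mask); n <- ncol(mask)
  lab <- matrix(0L, m, n)
  fg <- which(mask)
  if (!length(fg)) return(lab)
  dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  nn <- if (connectivity == "8") 8L else 4L
  dr <- dr[seq_len(nn)]; dc <- dc[seq_len(nn)]
  k <- 0L
  for (p in fg) {
    if (lab[p] != 0L) next
    k <- k + 1L
    stack <- p
    lab[p] <- k
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (q - 1L) %% m + 1L
      cc <- (q - 1L) %/% m + 1L
      nr <- r + dr; nc <- cc + dc
      ok <- nr >= 1L & nr <= m & nc >= 1L & nc <= n
      nb <- (nc[ok] - 1L) * m + nr[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- k
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

#' @describeIn labelComponents number of connected components.
#' @export
componentCount <- function(mask, connectivity = 8L)
  max(labelComponents(mask, connectivity))

## Binary dilation by the (2r+1)x(2r+1) square structuring element,
## implemented with shifts (used for the optional edge-tolerance band).
.dilateSquare <- function(mask, r = 1L) {
  if (r < 1L) return(mask)
  m <- nrow(mask); n <- ncol(mask)
  out <- mask
  for (dr in -r:r)
    for (dc in -r:r) {
      if (dr == 0L && dc == 0L) next
      src <- mask[max(1, 1 - dr):min(m, m - dr),
                  max(1, 1 - dc):min(n, n - dc), drop = FALSE]
      rr <- max(1, 1 + dr):min(m, m + dr)
      cc <- max(1, 1 + dc):min(n, n + dc)
      out[rr, cc] <- out[rr, cc] | src
    }
  out
}
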