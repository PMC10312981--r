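#' Extract the internal membrane of one cell
#'
#' The membrane is the internal boundary of the cell mask of the requested
#' width: the set of cell pixels within Chebyshev (8-connected) distance
#' `widthPx` of a non-cell pixel, computed as cell minus `widthPx` iterations
#' of 3x3 erosion. Pixels beyond the image edge count as non-cell, so cells
#' touching the border keep a defined membrane. Cells thinner than twice the
#' width are entirely membrane; remaining pixels are cytoplasm.
#'
#' @param mask a [LabelMask-class]
#' @param cellId positive integer label present in `mask`
#' @param widthPx membrane width in pixels (2 for histocytometry, 1 for IMC)
#' @return integer vector of column-major linear pixel indices into the mask
#' @examples
#' m <- matrix(0L, 7, 7); m[2:6, 2:6] <- 1L
#' length(extractMembrane(LabelMask(m), 1, 1))  # 16 perimeter pixels
#' length(extractMembrane(LabelMask(m), 1, 2))  # 24: only the centre is left
#' @export
extractMembrane <- function(mask, cellId, widthPx = 2L) {
  lab <- labelMatrix(mask)
  idx <- which(lab == cellId)
  if (!length(idx)) stop("cell ", cellId, " not present in mask")
  membraneFromLogical(lab == cellId, widthPx)
}

## membrane indices from a logical cell matrix
membraneFromLogical <- function(cell, widthPx) {
  core <- binErode8(cell, iterations = as.integer(widthPx))
  which(cell & !core)
}

## cytoplasm = cell minus membrane
cytoplasmFromLogical <- function(cell, widthPx) {
  core <- binErode8(cell, iterations = as.integer(widthPx))
  which(core)
}

#' Find the contact interfaces of one reference cell
#'
#' Each candidate neighbor's pixel set is dilated with a diamond (L1 ball)
#' structuring element of radius `dilationRadiusPx`; the intersection of the
#' dilated neighbor with the reference cell's membrane is the contact
#' interface. A record is emitted only when that intersection is nonempty.
#' Records are directional: the reference cell (a T cell in the published
#' analysis) owns the membrane being partitioned.
#'
#' @param mask a [LabelMask-class]
#' @param refId reference cell id
#' @param config an [AnalysisConfig-class] (membrane width, dilation radius)
#' @param neighborIds candidate neighbor ids; default: every other cell whose
#'   bounding box comes within reach of the reference cell
#' @param membranePx precomputed membrane of `refId` (linear indices);
#'   computed when `NULL`
#' @return data.frame with one row per contacting neighbor: `ref_id`,
#'   `neighbor_id`, `n_contact_px`, `border` (reference touches the image
#'   edge) and list-columns `contact_px`, `membrane_px` of linear indices
#' @export
findContacts <- function(mask, refId, config = cisaConfig(),
                         neighborIds = NULL, membranePx = NULL) {
  lab <- labelMatrix(mask)
  nr <- nrow(lab); nc <- ncol(lab)
  refIdx <- which(lab == refId)
  if (!length(refIdx)) stop("cell ", refId, " not present in mask")
  width <- config@membraneWidthPx
  radius <- config@dilationRadiusPx

  ## crop to the reference bounding box plus reach of dilation
  r <- ((refIdx - 1L) %% nr) + 1L
  c <- ((refIdx - 1L) %/% nr) + 1L
  border <- min(r) == 1L || max(r) == nr || min(c) == 1L || max(c) == nc
  pad <- radius + 1L
  r0 <- max(1L, min(r) - pad); r1 <- min(nr, max(r) + pad)
  c0 <- max(1L, min(c) - pad); c1 <- min(nc, max(c) + pad)
  crop <- lab[r0:r1, c0:c1, drop = FALSE]
  cnr <- nrow(crop)

  ## local <-> global linear index conversion
  toGlobal <- function(cidx) {
    rr <- ((cidx - 1L) %% cnr) + r0
    cc <- ((cidx - 1L) %/% cnr) + c0
    (cc - 1L) * nr + rr
  }

  if (is.null(membranePx)) {
    ## the crop pads the bounding box, so no reference pixel sits on the crop
    ## edge and erosion on the crop equals erosion on the full image
    membranePx <- toGlobal(membraneFromLogical(crop == refId, width))
  }
  memLocal <- matrix(FALSE, cnr, ncol(crop))
  mr <- ((membranePx - 1L) %% nr) + 1L
  mc <- ((membranePx - 1L) %/% nr) + 1L
  inCrop <- mr >= r0 & mr <= r1 & mc >= c0 & mc <= c1
  memLocal[cbind(mr[inCrop] - r0 + 1L, mc[inCrop] - c0 + 1L)] <- TRUE

  cand <- sort(unique(as.vector(crop)))
  cand <- cand[cand > 0L & cand != refId]
  if (!is.null(neighborIds)) cand <- intersect(cand, neighborIds)

  offs <- diamondOffsets(radius)
  rows <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    nb <- crop == cand[i]
    contact <- binDilate(nb, offs) & memLocal
    if (!any(contact)) next
    rows[[i]] <- data.frame(
      ref_id = refId, neighbor_id = cand[i],
      n_contact_px = sum(contact), border = border
    )
    rows[[i]]$contact_px <- list(toGlobal(which(contact)))
    rows[[i]]$membrane_px <- list(membranePx)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    out <- data.frame(ref_id = integer(0), neighbor_id = integer(0),
                      n_contact_px = integer(0), border = logical(0))
    out$contact_px <- list(); out$membrane_px <- list()
    return(out)
  }
  do.call(rbind, rows)
}

#' Partition membranes into contact and non-contact sets per target type
#'
#' For every reference cell, finds all contacting neighbors and, for each
#' neighbor holding a target type, attaches the non-contact pool for that
#' type: the membrane minus the union of contact pixels over *all* neighbors
#' of that type. A reference touching several same-type neighbors therefore
#' scores each contact against one shared non-contact pool. Neighbors of
#' other types do not reduce the pool.
#'
#' @param mask a [LabelMask-class]
#' @param cellTable cell table with `id` and `types` columns
#' @param config an [AnalysisConfig-class]; `referenceTypes` selects the
#'   reference cells, `targetTypes` the neighbors to score against
#' @param refIds explicit reference ids (overrides type selection)
#' @return data.frame of contact records: `ref_id`, `neighbor_id`,
#'   `neighbor_types`, `target_type`, `n_contact_px`, `n_noncontact_px`,
#'   `border`, `no_noncontact` flag, and list-columns `contact_px`,
#'   `noncontact_px`, `membrane_px`
#' @export
computeContacts <- function(mask, cellTable, config = cisaConfig(),
                            refIds = NULL) {
  cellTable <- validateCellTable(cellTable, mask)
  if (is.null(refIds))
    refIds <- cellTable$id[hasType(cellTable$types, config@referenceTypes)]
  typeOf <- stats::setNames(cellTable$types, cellTable$id)
  out <- vector("list", length(refIds))
  for (k in seq_along(refIds)) {
    rec <- findContacts(mask, refIds[k], config)
    if (!nrow(rec)) next
    rec$neighbor_types <- unname(typeOf[as.character(rec$neighbor_id)])
    rec$neighbor_types[is.na(rec$neighbor_types)] <- ""
    sub <- vector("list", length(config@targetTypes))
    for (t in seq_along(config@targetTypes)) {
      tt <- config@targetTypes[t]
      ofType <- hasType(rec$neighbor_types, tt)
      if (!any(ofType)) next
      pool <- setdiff(rec$membrane_px[[1L]],
                      unlist(rec$contact_px[ofType]))
      s <- rec[ofType, , drop = FALSE]
      s$target_type <- tt
      s$noncontact_px <- rep(list(pool), nrow(s))
      s$n_noncontact_px <- length(pool)
      s$no_noncontact <- length(pool) == 0L
      sub[[t]] <- s
    }
    sub <- sub[!vapply(sub, is.null, logical(1L))]
    if (length(sub)) out[[k]] <- do.call(rbind, sub)
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) {
    empty <- data.frame(ref_id = integer(0), neighbor_id = integer(0),
                        neighbor_types = character(0),
                        target_type = character(0),
                        n_contact_px = integer(0),
                        n_noncontact_px = integer(0),
                        border = logical(0), no_noncontact = logical(0))
    empty$contact_px <- list(); empty$noncontact_px <- list()
    empty$membrane_px <- list()
    return(empty)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
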