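## Synthetic tissue, point-pattern, and two-compartment image generators.
## These define the study conditions every other module is validated under:
## packed disk cells with membrane-localized markers, designated contacting
## pairs with a known contact-directed polarization factor, background
## noise, and Poisson / clustered point patterns for the RDF statistics.

#' Configuration of the synthetic tissue generator
#'
#' @param imageSizePx square image side (default 300)
#' @param pixelSizeUm um per pixel (default 1)
#' @param cellRadiusPx inclusive integer range of cell radii (default 5..6)
#' @param nPairs designated contacting reference-target pairs (default 20)
#' @param nSingles additional isolated cells (default 20); a third of them
#'   (rounded down, at least one when any) are unlabeled background cells so
#'   a noise term is always estimable
#' @param refType,targetType,otherType type labels (defaults `"Tcell"`,
#'   `"APC"`, `"Other"`)
#' @param markers marker channel names; the first is the scored synapse
#'   marker on reference membranes (default `"CD3"`)
#' @param membraneBaseIntensity mean membrane intensity of the scored
#'   markers (default 25 — at Poisson noise this gives SNR
#'   sqrt(25) = 5)
#' @param cytoplasmIntensity interior intensity (default 2)
#' @param polarizationFactor f >= 1 multiplying reference membrane pixels
#'   facing the designated neighbor; ground truth sigma = log2(f)
#' @param comarkerRho correlation of the two markers' per-contact log2
#'   polarization around log2(f) when two markers are simulated
#' @param polarizationSdLog2 sd of the per-contact log2 polarization
#'   (default 0: all contacts share f)
#' @param baseIntensitySdLog2 sd of the per-cell log2 membrane base
#'   intensity, independent between markers (default 0)
#' @param noise `"none"`, `"gaussian"` (additive, clipped at 0) or
#'   `"poisson"` (counts; produces exact-zero pixels as in IMC)
#' @param backgroundNoiseSd sd of the Gaussian option (default 2)
#' @param membraneWidthPx membrane ring width used for painting (default 2)
#' @param dilationRadiusPx radius of the diamond defining the painted
#'   contact zone — the same rule the analyzer uses, so ground truth is
#'   exact (default 2)
#' @param seed RNG seed
#' @return named list of settings for [generateTissue()]
#' @export
syntheticTissueConfig <- function(imageSizePx = 300L, pixelSizeUm = 1,
                                  cellRadiusPx = c(5L, 6L), nPairs = 20L,
                                  nSingles = 20L, refType = "Tcell",
                                  targetType = "APC", otherType = "Other",
                                  markers = "CD3",
                                  membraneBaseIntensity = 25,
                                  cytoplasmIntensity = 2,
                                  polarizationFactor = 2,
                                  comarkerRho = 0.9,
                                  polarizationSdLog2 = 0,
                                  baseIntensitySdLog2 = 0,
                                  noise = c("none", "gaussian", "poisson"),
                                  backgroundNoiseSd = 2,
                                  membraneWidthPx = 2L,
                                  dilationRadiusPx = 2L,
                                  seed = 1L) {
  stopifnot(polarizationFactor >= 1, imageSizePx > 0,
            all(cellRadiusPx > 0))
  list(imageSizePx = as.integer(imageSizePx), pixelSizeUm = pixelSizeUm,
       cellRadiusPx = as.integer(cellRadiusPx), nPairs = as.integer(nPairs),
       nSingles = as.integer(nSingles), refType = refType,
       targetType = targetType, otherType = otherType, markers = markers,
       membraneBaseIntensity = membraneBaseIntensity,
       cytoplasmIntensity = cytoplasmIntensity,
       polarizationFactor = polarizationFactor, comarkerRho = comarkerRho,
       polarizationSdLog2 = polarizationSdLog2,
       baseIntensitySdLog2 = baseIntensitySdLog2,
       noise = match.arg(noise), backgroundNoiseSd = backgroundNoiseSd,
       membraneWidthPx = as.integer(membraneWidthPx),
       dilationRadiusPx = as.integer(dilationRadiusPx),
       seed = as.integer(seed))
}

## disk pixel indices around an integer centre
diskIdx <- function(cr, cc, radius, nr, nc) {
  rs <- max(1L, cr - radius):min(nr, cr + radius)
  cs <- max(1L, cc - radius):min(nc, cc + radius)
  g <- expand.grid(r = rs, c = cs)
  g <- g[(g$r - cr)^2 + (g$c - cc)^2 <= radius^2, , drop = FALSE]
  (g$c - 1L) * nr + g$r
}

#' Generate a synthetic tissue with known synapse ground truth
#'
#' Places non-overlapping disk cells on a jittered grid. Designated pairs
#' are tangent (1-pixel gap between masks, bridged by the radius-2 diamond
#' dilation); all other cells are isolated. Marker channels paint each
#' cell's internal membrane ring at a base intensity and the interior at a
#' low cytoplasm level; on reference cells of designated pairs, membrane
#' pixels inside the dilation-defined contact zone are multiplied by the
#' polarization factor, so the noiseless measured sigma equals log2(f)
#' exactly. Optional Gaussian or Poisson noise is applied afterwards.
#'
#' @param config from [syntheticTissueConfig()]
#' @return list with `image` ([MarkerImage-class]), `mask`
#'   ([LabelMask-class]), `cellTable`, and `truth` (per designated contact:
#'   `ref_id`, `neighbor_id`, and `true_log2_polarization_<marker>`)
#' @export
generateTissue <- function(config = syntheticTissueConfig()) {
  withLocalSeed(config$seed, generateTissueImpl(config))
}

generateTissueImpl <- function(config) {
  n <- config$imageSizePx
  rmax <- max(config$cellRadiusPx)
  spacing <- 4L * rmax + 6L
  margin <- 2L * rmax + 4L
  sites <- expand.grid(
    r = seq(margin, n - margin, by = spacing),
    c = seq(margin, n - margin, by = spacing)
  )
  need <- config$nPairs + config$nSingles
  if (nrow(sites) < need)
    stop("placement failure: ", need, " cells requested but only ",
         nrow(sites), " grid sites fit; lower density or enlarge the image")
  sites <- sites[sample.int(nrow(sites), need), , drop = FALSE]

  lab <- matrix(0L, n, n)
  nmk <- length(config$markers)
  channels <- rep(list(matrix(0, n, n)), nmk)
  names(channels) <- config$markers
  radius <- function() sample(config$cellRadiusPx[1L]:config$cellRadiusPx[2L], 1L)
  types <- character(0)
  cellPx <- list()
  nextId <- 0L
  addCell <- function(cr, cc, rad, type) {
    nextId <<- nextId + 1L
    px <- diskIdx(cr, cc, rad, n, n)
    lab[px] <<- nextId
    cellPx[[nextId]] <<- px
    types <<- c(types, type)
    nextId
  }

  ## per-contact polarization: shared latent + marker-specific component
  rho <- config$comarkerRho
  sdl <- config$polarizationSdLog2
  drawPolarization <- function() {
    z <- rnorm(1L)
    eps <- rnorm(nmk)
    log2(config$polarizationFactor) +
      sdl * (rho * z + sqrt(max(0, 1 - rho^2)) * eps)
  }

  truth <- NULL
  contactZones <- list()
  for (p in seq_len(config$nPairs)) {
    cr <- sites$r[p]; cc <- sites$c[p]
    r1 <- radius(); r2 <- radius()
    dir <- sample(list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L)), 1L)[[1L]]
    off <- r1 + r2 + 1L                     # 1-px gap between the two masks
    refId <- addCell(cr, cc, r1, config$refType)
    nbId <- addCell(cr + dir[1L] * off, cc + dir[2L] * off, r2,
                    config$targetType)
    pol <- drawPolarization()
    truth <- rbind(truth, data.frame(
      ref_id = refId, neighbor_id = nbId,
      matrix(pol, nrow = 1L,
             dimnames = list(NULL, paste0("true_log2_polarization_",
                                          config$markers)))))
    contactZones[[p]] <- list(ref = refId, nb = nbId, pol = pol)
  }
  nOther <- if (config$nSingles > 0L) max(1L, config$nSingles %/% 3L) else 0L
  for (s in seq_len(config$nSingles)) {
    i <- config$nPairs + s
    type <- if (s <= nOther) config$otherType
            else if (s %% 2L == 0L) config$refType else config$targetType
    addCell(sites$r[i], sites$c[i], radius(), type)
  }

  mask <- LabelMask(lab)
  ## crop-local morphology: cells are compact, so membranes and contact
  ## zones are computed on small windows and mapped back to the image
  cropAround <- function(ids, pad) {
    idx <- unlist(cellPx[ids])
    r <- ((idx - 1L) %% n) + 1L
    c <- ((idx - 1L) %/% n) + 1L
    r0 <- max(1L, min(r) - pad); r1 <- min(n, max(r) + pad)
    c0 <- max(1L, min(c) - pad); c1 <- min(n, max(c) + pad)
    list(m = lab[r0:r1, c0:c1, drop = FALSE], r0 = r0, c0 = c0,
         nr = r1 - r0 + 1L)
  }
  toGlobal <- function(crop, cidx) {
    rr <- ((cidx - 1L) %% crop$nr) + crop$r0
    cc <- ((cidx - 1L) %/% crop$nr) + crop$c0
    (cc - 1L) * n + rr
  }
  ## paint membranes: base intensity per (cell, marker), cytoplasm low
  offs <- diamondOffsets(config$dilationRadiusPx)
  ids <- seq_len(nextId)
  baseOf <- matrix(config$membraneBaseIntensity, nextId, nmk)
  if (config$baseIntensitySdLog2 > 0)
    baseOf <- baseOf * 2^matrix(rnorm(nextId * nmk,
                                      sd = config$baseIntensitySdLog2),
                                nextId, nmk)
  for (id in ids) {
    crop <- cropAround(id, config$membraneWidthPx + 1L)
    cell <- crop$m == id
    mem <- toGlobal(crop, membraneFromLogical(cell, config$membraneWidthPx))
    cyto <- toGlobal(crop, cytoplasmFromLogical(cell, config$membraneWidthPx))
    for (m in seq_len(nmk)) {
      channels[[m]][mem] <- baseOf[id, m]
      channels[[m]][cyto] <- config$cytoplasmIntensity
    }
  }
  ## multiply contact-facing reference membrane pixels by the factor
  for (z in contactZones) {
    crop <- cropAround(c(z$ref, z$nb), config$dilationRadiusPx + 1L)
    mem <- membraneFromLogical(crop$m == z$ref, config$membraneWidthPx)
    zone <- which(binDilate(crop$m == z$nb, offs))
    hit <- toGlobal(crop, intersect(mem, zone))
    for (m in seq_len(nmk))
      channels[[m]][hit] <- channels[[m]][hit] * 2^z$pol[m]
  }
  channels <- lapply(channels, function(ch) {
    switch(config$noise,
           none = ch,
           gaussian = pmax(ch + matrix(rnorm(n * n,
                                             sd = config$backgroundNoiseSd),
                                       n, n), 0),
           poisson = matrix(rpois(n * n, lambda = ch), n, n))
  })
  image <- MarkerImage(channels, pixelSize = config$pixelSizeUm)
  cellTable <- makeCellTable(mask, image)
  cellTable$types <- types[cellTable$id]
  list(image = image, mask = mask, cellTable = cellTable, truth = truth,
       config = config)
}

#' Generate a spatial point pattern for RDF calibration
#'
#' `"poisson"`: a homogeneous Poisson process — N ~ Poisson(lambda * area),
#' positions uniform, type labels independent with the given proportions.
#' `"clustered"`: Poisson parents of the reference type, each with
#' Poisson-distributed offspring of the target type placed uniformly within
#' `clusterRadiusUm`.
#'
#' @param kind `"poisson"` or `"clustered"`
#' @param lambdaPerMm2 intensity (points or parents per mm^2)
#' @param windowUm rectangle `c(xmin, xmax, ymin, ymax)` in um
#' @param typeProportions named proportions of type labels (poisson kind)
#' @param offspringPerParent mean offspring per parent (clustered kind)
#' @param clusterRadiusUm offspring placement radius (default 15)
#' @param seed RNG seed
#' @return cell table (`id`, `x_um`, `y_um`, `types`, `region = "none"`)
#' @export
generatePointPattern <- function(kind = c("poisson", "clustered"),
                                 lambdaPerMm2 = 100,
                                 windowUm = c(0, 1000, 0, 1000),
                                 typeProportions = c(Tcell = 0.5, APC = 0.5),
                                 offspringPerParent = 5,
                                 clusterRadiusUm = 15,
                                 seed = 1L) {
  kind <- match.arg(kind)
  withLocalSeed(seed, {
    areaMm2 <- (windowUm[2L] - windowUm[1L]) * (windowUm[4L] - windowUm[3L]) / 1e6
    if (kind == "poisson") {
      nPts <- rpois(1L, lambdaPerMm2 * areaMm2)
      x <- runif(nPts, windowUm[1L], windowUm[2L])
      y <- runif(nPts, windowUm[3L], windowUm[4L])
      types <- if (nPts) sample(names(typeProportions), nPts, replace = TRUE,
                                prob = typeProportions) else character(0)
    } else {
      nPar <- rpois(1L, lambdaPerMm2 * areaMm2)
      px <- runif(nPar, windowUm[1L], windowUm[2L])
      py <- runif(nPar, windowUm[3L], windowUm[4L])
      nOff <- if (nPar) rpois(nPar, offspringPerParent) else integer(0)
      theta <- runif(sum(nOff), 0, 2 * pi)
      rad <- clusterRadiusUm * sqrt(runif(sum(nOff)))
      x <- c(px, rep(px, nOff) + rad * cos(theta))
      y <- c(py, rep(py, nOff) + rad * sin(theta))
      keep <- x >= windowUm[1L] & x <= windowUm[2L] &
        y >= windowUm[3L] & y <= windowUm[4L]
      types <- c(rep(names(typeProportions)[1L], nPar),
                 rep(names(typeProportions)[2L], sum(nOff)))[keep]
      x <- x[keep]; y <- y[keep]
    }
    data.frame(id = seq_along(x), x_um = x, y_um = y, types = types,
               region = rep("none", length(x)), stringsAsFactors = FALSE)
  })
}

#' Generate a two-compartment (tumor blob + leukocyte field) image
#'
#' Emulates the four intensity populations the adaptive 4-class Multi-Otsu
#' segmentation expects: a non-tissue margin (near zero), a dim tissue
#' background, and block-textured foreground staining with interleaved low-
#' and high-intensity patches (heterogeneous marker expression). The tumor
#' channel's foreground is a disk; the leukocyte channel's foreground is the
#' rest of the tissue, so the derived stroma excludes the blob. Additive
#' Gaussian noise is clipped at 0. The true compartment masks are returned
#' alongside.
#'
#' @param imageSizePx square image side (default 360)
#' @param marginPx non-tissue border width (default 30)
#' @param blobRadiusPx tumor blob radius (default 80; ~20k px, well above
#'   the 2500 px object filter)
#' @param foregroundHigh,foregroundLow two-level foreground means (defaults
#'   200 and 60), mixed as `blockPx`-sized patches
#' @param blockPx texture patch side in pixels (default 4)
#' @param lowFraction fraction of low-intensity patches (default 0.3)
#' @param tissueBackground tissue background mean (default 8)
#' @param nonTissueBackground non-tissue margin mean (default 1)
#' @param noiseSd additive Gaussian noise sd, clipped at 0 (default 6)
#' @param tumorChannel,leukocyteChannel channel names
#' @param seed RNG seed
#' @return list with `image` ([MarkerImage-class]) and `truth`
#'   ([RegionMasks-class]: tumor = blob, stroma = tissue minus blob)
#' @export
generateTwoCompartmentImage <- function(imageSizePx = 360L,
                                        marginPx = 30L,
                                        blobRadiusPx = 80L,
                                        foregroundHigh = 200,
                                        foregroundLow = 60,
                                        blockPx = 4L,
                                        lowFraction = 0.3,
                                        tissueBackground = 8,
                                        nonTissueBackground = 1,
                                        noiseSd = 6,
                                        tumorChannel = "Melanoma",
                                        leukocyteChannel = "CD45",
                                        seed = 1L) {
  withLocalSeed(seed, {
    n <- imageSizePx
    tissue <- matrix(FALSE, n, n)
    tissue[(marginPx + 1L):(n - marginPx), (marginPx + 1L):(n - marginPx)] <- TRUE
    cr <- n %/% 2L; cc <- n %/% 2L
    blob <- matrix(FALSE, n, n)
    blob[diskIdx(cr, cc, blobRadiusPx, n, n)] <- TRUE
    blob <- blob & tissue
    field <- tissue & !blob
    ## blockPx-sized two-level texture shared grid, independent per channel
    texture <- function() {
      nb <- ceiling(n / blockPx)
      lv <- matrix(sample(c(foregroundLow, foregroundHigh), nb * nb,
                          replace = TRUE,
                          prob = c(lowFraction, 1 - lowFraction)), nb, nb)
      lv[ceiling(row(matrix(0, n, n)) / blockPx) +
           (ceiling(col(matrix(0, n, n)) / blockPx) - 1L) * nb]
    }
    paint <- function(fg) {
      m <- matrix(nonTissueBackground, n, n)
      m[tissue] <- tissueBackground
      tex <- matrix(texture(), n, n)
      m[fg] <- tex[fg]
      pmax(m + matrix(rnorm(n * n, sd = noiseSd), n, n), 0)
    }
    channels <- stats::setNames(list(paint(blob), paint(field)),
                                c(tumorChannel, leukocyteChannel))
    list(image = MarkerImage(channels),
         truth = RegionMasks(tumor = blob, stroma = field))
  })
}
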