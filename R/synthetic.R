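#' @include core-data.R
NULL

## Pattern-class vocabulary ---------------------------------------------------

.pureClasses <- c("nuclear", "nucleolar", "nucleolar_rim", "cytosolic",
                  "punctate", "membrane")

#' Parse a pattern-class string
#'
#' Pure classes are one of \code{nuclear}, \code{nucleolar},
#' \code{nucleolar_rim}, \code{cytosolic}, \code{punctate}, \code{membrane};
#' a mixture is written \code{"mixture(classA,classB,alpha)"} and renders as
#' \code{alpha * classA + (1 - alpha) * classB}.
#'
#' @param x a single pattern-class string.
#' @return A list with \code{kind} ("pure"/"mixture") and components.
#' @export
parsePatternClass <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (x %in% .pureClasses) return(list(kind = "pure", name = x))
  m <- regmatches(x, regexec(
    "^mixture\\(([a-z_]+),([a-z_]+),([0-9.]+)\\)$", x))[[1]]
  if (length(m) == 4L && m[2] %in% .pureClasses && m[3] %in% .pureClasses) {
    alpha <- as.numeric(m[4])
    if (is.finite(alpha) && alpha >= 0 && alpha <= 1)
      return(list(kind = "mixture", a = m[2], b = m[3], alpha = alpha))
  }
  stop("contract error: unknown pattern class '", x, "'")
}

#' Format a mixture pattern-class string
#'
#' @param classA,classB pure class names.
#' @param alpha mixing fraction in [0, 1]; 1 renders pure \code{classA}.
#' @export
mixtureClass <- function(classA, classB, alpha) {
  sprintf("mixture(%s,%s,%g)", classA, classB, alpha)
}

#' Default synthetic benchmark specification
#'
#' The defaults are the benchmark every evaluation in this package runs on:
#' 6 localization classes x 30 images x 10-16 cells on 256 x 256 fields,
#' with per-image gain and planar illumination-gradient nuisance, additive
#' noise, and per-cell intensity jitter. Cell bodies are rotated ellipses of
#' 12.5-13.5 px radius (body area always above the 400 px nucleus-detection
#' area threshold, while a whole cell still fits a 32 px crop); the nucleus
#' is a concentric smaller ellipse.
#'
#' @param patternClasses character vector of pattern classes.
#' @param imagesPerClass images (wells) per class.
#' @param cellsPerImage integer (min, max) cells per field of view.
#' @param fieldSize field-of-view size in px, (rows, cols).
#' @param fieldsPerImage fields of view per image (well).
#' @param radiusRange cell effective radius range, px.
#' @param eccentricityRange axis-ratio range (area-preserving).
#' @param nucleusFractionRange nucleus radius as a fraction of cell radius.
#' @param gainRange per-image multiplicative gain range.
#' @param rampAmplitude planar illumination gradient amplitude (+/- fraction).
#' @param noiseSd additive Gaussian noise sd (on the [0,1] intensity scale).
#' @param cellJitterSd sd of the per-cell log-normal intensity jitter
#'   (protein expression varies several-fold across genetically identical
#'   cells).
#' @param diffuseFractionRange per-cell range of the fraction of protein in
#'   an unlocalized diffuse pool over the whole cell body (the standard
#'   confound of tagged-protein screens).
#' @param psfSigma Gaussian point-spread sigma in px; when a (min, max)
#'   range is given, one value is drawn per image, emulating field-to-field
#'   focus variation.
#' @param backgroundRange per-image additive autofluorescence background
#'   level range (multiplied by the image gain), applied to all channels.
#' @param mixtureKappa concentration of the per-cell Beta blend draw for
#'   mixture classes; endpoints alpha = 0, 1 stay exactly pure.
#' @param structuralChannels 1 (body + nucleus in one marker channel) or 2
#'   (separate nucleus and body channels).
#' @param seed integer; fully determines the dataset.
#' @return A \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(patternClasses = .pureClasses,
                          imagesPerClass = 30,
                          cellsPerImage = c(10, 16),
                          fieldSize = c(256, 256),
                          fieldsPerImage = 1,
                          radiusRange = c(12.5, 13.5),
                          eccentricityRange = c(1, 1.4),
                          nucleusFractionRange = c(0.35, 0.55),
                          gainRange = c(0.7, 1.3),
                          rampAmplitude = 0.15,
                          noiseSd = 0.12,
                          cellJitterSd = 0.4,
                          diffuseFractionRange = c(0.1, 0.4),
                          psfSigma = c(0.8, 1.6),
                          backgroundRange = c(0, 0.15),
                          mixtureKappa = 8,
                          structuralChannels = 1,
                          seed = 1) {
  new("SyntheticSpec",
      patternClasses = as.character(patternClasses),
      imagesPerClass = as.integer(imagesPerClass),
      cellsPerImage = as.integer(cellsPerImage),
      fieldSize = as.integer(fieldSize),
      fieldsPerImage = as.integer(fieldsPerImage),
      radiusRange = as.numeric(radiusRange),
      eccentricityRange = as.numeric(eccentricityRange),
      nucleusFractionRange = as.numeric(nucleusFractionRange),
      gainRange = as.numeric(gainRange),
      rampAmplitude = as.numeric(rampAmplitude),
      noiseSd = as.numeric(noiseSd),
      cellJitterSd = as.numeric(cellJitterSd),
      diffuseFractionRange = as.numeric(diffuseFractionRange),
      psfSigma = as.numeric(psfSigma),
      backgroundRange = as.numeric(backgroundRange),
      mixtureKappa = as.numeric(mixtureKappa),
      structuralChannels = as.integer(structuralChannels),
      seed = as.integer(seed))
}

## Rendering ------------------------------------------------------------------

# squared normalized elliptical radius on a pixel grid centred at (cy, cx)
.ellipseR2 <- function(rows, cols, cy, cx, a, b, theta) {
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u * u + v * v
}

.gaussBlob <- function(rows, cols, cy, cx, sigma) {
  dy2 <- (rows - cy)^2
  dx2 <- (cols - cx)^2
  outer(exp(-dy2 / (2 * sigma^2)), exp(-dx2 / (2 * sigma^2)))
}

#' Sample a cell morphology
#'
#' @param spec a \linkS4class{SyntheticSpec}; draws radius, eccentricity,
#'   rotation and nucleus fraction from its ranges (consumes the R RNG).
#' @return A morphology list with semi-axes \code{a}, \code{b}, rotation
#'   \code{theta}, nucleus fraction and offset, and \code{patchSize}.
#' @export
sampleMorphology <- function(spec) {
  r <- stats::runif(1, spec@radiusRange[1], spec@radiusRange[2])
  e <- stats::runif(1, spec@eccentricityRange[1], spec@eccentricityRange[2])
  list(a = r * sqrt(e), b = r / sqrt(e),
       theta = stats::runif(1, 0, pi),
       nucleusFrac = stats::runif(1, spec@nucleusFractionRange[1],
                                  spec@nucleusFractionRange[2]),
       nucOffsetRow = stats::rnorm(1, 0, 0.6),
       nucOffsetCol = stats::rnorm(1, 0, 0.6),
       patchSize = 2L * as.integer(ceiling(r * sqrt(e))) + 7L)
}

# protein intensity map for a pure class on a prepared geometry
.renderProtein <- function(geom, name) {
  with(geom, switch(
    name,
    nuclear = 0.9 * nucMask + 0.06 * cytoMask,
    nucleolar = {
      nb <- sample.int(3L, 1L)
      img <- 0.08 * nucMask
      for (i in seq_len(nb)) {
        # blob centre uniform inside 55% of the nucleus ellipse
        phi <- stats::runif(1, 0, 2 * pi)
        rr <- 0.55 * sqrt(stats::runif(1))
        bc <- nucCenter + rr * c(na * cos(phi), nb2 * sin(phi))
        img <- img + 0.95 * .gaussBlob(rows, cols, bc[1], bc[2], 1.4) * nucMask
      }
      pmin(img, 1)
    },
    nucleolar_rim = {
      rn <- sqrt(rn2)
      0.9 * ((rn >= 0.78 & rn <= 1.08) * 1) + 0.08 * nucMask
    },
    cytosolic = 0.8 * cytoMask + 0.1 * nucMask,
    punctate = {
      nf <- 1L + stats::rpois(1L, 5)
      img <- 0.08 * bodyMask
      for (i in seq_len(nf)) {
        phi <- stats::runif(1, 0, 2 * pi)
        rr <- 0.85 * sqrt(stats::runif(1))
        bc <- center + rr * c(a * cos(phi), b * sin(phi))
        img <- img + 0.95 * .gaussBlob(rows, cols, bc[1], bc[2], 1.2) * bodyMask
      }
      pmin(img, 1)
    },
    membrane = {
      rb <- sqrt(rb2)
      0.85 * ((rb >= 0.80 & rb <= 1.04) * 1) + 0.07 * bodyMask
    },
    stop("contract error: unknown pattern class '", name, "'")))
}

#' Render one synthetic cell
#'
#' Draws a square patch containing one cell: structural channel(s) depicting
#' the cell body and nucleus, and a protein channel realizing the pattern
#' class. Mixtures render both components and blend them
#' \code{alpha * A + (1 - alpha) * B}. Consumes the R RNG (blob/focus
#' placement); seed the RNG for reproducible patches.
#'
#' @param morphology a morphology from \code{\link{sampleMorphology}}.
#' @param patternClass a pattern-class string (see
#'   \code{\link{parsePatternClass}}).
#' @param structuralChannels 1 or 2.
#' @param diffuseFraction fraction of the protein signal spread uniformly
#'   over the cell body instead of the localized pattern.
#' @return A list with \code{structural} (list of matrices) and
#'   \code{protein} (matrix), values in [0, 1].
#' @export
renderCell <- function(morphology, patternClass, structuralChannels = 1,
                       diffuseFraction = 0) {
  pc <- parsePatternClass(patternClass)
  p <- morphology$patchSize
  ctr <- (p + 1) / 2
  rows <- seq_len(p)
  cols <- seq_len(p)
  a <- morphology$a
  b <- morphology$b
  th <- morphology$theta
  nf <- morphology$nucleusFrac
  nucCenter <- c(ctr + morphology$nucOffsetRow, ctr + morphology$nucOffsetCol)
  rb2 <- .ellipseR2(rows, cols, ctr, ctr, a, b, th)
  rn2 <- .ellipseR2(rows, cols, nucCenter[1], nucCenter[2],
                    nf * a, nf * b, th)
  geom <- list(rows = rows, cols = cols, center = c(ctr, ctr),
               nucCenter = nucCenter, a = a, b = b,
               na = nf * a, nb2 = nf * b,
               rb2 = rb2, rn2 = rn2,
               bodyMask = (rb2 <= 1) * 1,
               nucMask = (rn2 <= 1) * 1)
  geom$cytoMask <- geom$bodyMask * (1 - geom$nucMask)
  protein <- if (pc$kind == "pure") {
    .renderProtein(geom, pc$name)
  } else {
    pa <- .renderProtein(geom, pc$a)
    pb <- .renderProtein(geom, pc$b)
    pc$alpha * pa + (1 - pc$alpha) * pb
  }
  if (diffuseFraction > 0)
    protein <- (1 - diffuseFraction) * protein +
      diffuseFraction * 0.5 * geom$bodyMask
  structural <- if (structuralChannels == 1L) {
    list(0.6 * geom$bodyMask + 0.4 * geom$nucMask)
  } else {
    list(0.85 * geom$nucMask + 0.05 * geom$bodyMask,  # nucleus stain
         0.40 * geom$bodyMask)                        # body / microtubule
  }
  list(structural = structural, protein = protein)
}

## Field assembly -------------------------------------------------------------

# Poisson-disc-style rejection placement; bounded retries.
.placeCenters <- function(n, fieldSize, margin, minDist, maxTries = 4000L) {
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(centers) < n) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop("contract error: field too small to place ", n,
           " cells without overlap")
    cand <- c(stats::runif(1, margin, fieldSize[1] - margin),
              stats::runif(1, margin, fieldSize[2] - margin))
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                           byrow = TRUE))^2)) >= minDist))
      centers <- rbind(centers, cand)
  }
  centers
}

# per-cell mixture blend: Beta draw with mean alpha; exact at the endpoints
.drawCellAlpha <- function(alpha, kappa) {
  if (alpha <= 0) return(0)
  if (alpha >= 1) return(1)
  stats::rbeta(1, alpha * kappa, (1 - alpha) * kappa)
}

#' Generate one synthetic image (well)
#'
#' Places cells without overlap, renders each cell's channels, applies the
#' per-image gain and planar illumination gradient to all channels, adds
#' Gaussian noise, and records ground-truth centers in the metadata.
#' Consumes the R RNG.
#'
#' @param imageId identifier for the image.
#' @param patternClass pattern-class string shared by all cells of the image.
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return A \linkS4class{MicroscopyImage} whose metadata holds
#'   \code{pattern_class} and a \code{centers} data.frame (0-based
#'   field_index, row, col).
#' @export
generateImage <- function(imageId, patternClass, spec) {
  pc <- parsePatternClass(patternClass)  # validates
  if (spec@cellsPerImage[1] < 1L)
    stop("contract error: cellsPerImage must be >= 1")
  H0 <- spec@fieldSize[1]
  W0 <- spec@fieldSize[2]
  nchan <- spec@structuralChannels + 1L
  amax <- spec@radiusRange[2] * sqrt(spec@eccentricityRange[2])
  margin <- ceiling(amax) + 3
  minDist <- 2 * amax + 3
  gain <- stats::runif(1, spec@gainRange[1], spec@gainRange[2])
  rampPhi <- stats::runif(1, 0, 2 * pi)
  psf <- if (length(spec@psfSigma) > 1L)
    stats::runif(1, spec@psfSigma[1], spec@psfSigma[2]) else spec@psfSigma
  bg <- if (length(spec@backgroundRange) && max(spec@backgroundRange) > 0)
    stats::runif(1, spec@backgroundRange[1], spec@backgroundRange[2]) else 0
  fields <- vector("list", spec@fieldsPerImage)
  centers <- NULL
  for (fi in seq_len(spec@fieldsPerImage)) {
    n <- if (spec@cellsPerImage[1] == spec@cellsPerImage[2])
      spec@cellsPerImage[1] else
        sample(spec@cellsPerImage[1]:spec@cellsPerImage[2], 1L)
    pos <- .placeCenters(n, c(H0, W0), margin, minDist)
    chans <- replicate(nchan, matrix(0, H0, W0), simplify = FALSE)
    for (k in seq_len(n)) {
      morph <- sampleMorphology(spec)
      cls <- patternClass
      if (pc$kind == "mixture") {
        aCell <- .drawCellAlpha(pc$alpha, spec@mixtureKappa)
        cls <- mixtureClass(pc$a, pc$b, aCell)
      }
      df <- stats::runif(1, spec@diffuseFractionRange[1],
                         spec@diffuseFractionRange[2])
      patch <- renderCell(morph, cls, spec@structuralChannels,
                          diffuseFraction = df)
      jp <- exp(stats::rnorm(1, 0, spec@cellJitterSd))
      js <- exp(stats::rnorm(1, 0, spec@cellJitterSd / 4))
      p <- morph$patchSize
      half <- (p - 1) / 2
      r0 <- round(pos[k, 1]) - half
      c0 <- round(pos[k, 2]) - half
      rr <- r0:(r0 + p - 1)
      cc <- c0:(c0 + p - 1)
      okr <- rr >= 1 & rr <= H0
      okc <- cc >= 1 & cc <= W0
      for (z in seq_len(spec@structuralChannels))
        chans[[z]][rr[okr], cc[okc]] <- chans[[z]][rr[okr], cc[okc]] +
          js * patch$structural[[z]][okr, okc]
      chans[[nchan]][rr[okr], cc[okc]] <- chans[[nchan]][rr[okr], cc[okc]] +
        jp * patch$protein[okr, okc]
    }
    # planar multiplicative illumination ramp, shared by all channels
    ry <- (seq_len(H0) - (H0 + 1) / 2) / H0
    rx <- (seq_len(W0) - (W0 + 1) / 2) / W0
    ramp <- 1 + spec@rampAmplitude *
      (outer(ry, rep(1, W0)) * sin(rampPhi) + outer(rep(1, H0), rx) * cos(rampPhi)) * 2
    field <- array(0, dim = c(H0, W0, nchan))
    for (z in seq_len(nchan)) {
      ch <- (chans[[z]] + bg) * gain * ramp
      if (psf > 0) ch <- EBImage::gblur(ch, sigma = psf)
      if (spec@noiseSd > 0)
        ch <- ch + matrix(stats::rnorm(H0 * W0, 0, spec@noiseSd), H0, W0)
      field[, , z] <- pmax(ch, 0)
    }
    fields[[fi]] <- field
    centers <- rbind(centers,
                     data.frame(field_index = fi - 1L,
                                row = round(pos[, 1]) - 1,
                                col = round(pos[, 2]) - 1))
  }
  chn <- if (spec@structuralChannels == 1L) c("marker", "protein") else
    c("nucleus", "body", "protein")
  layout <- ChannelLayout(chn, structural = seq_len(nchan - 1L),
                          protein = nchan)
  new("MicroscopyImage", imageId = as.character(imageId), fields = fields,
      layout = layout,
      metadata = list(pattern_class = patternClass, centers = centers))
}

.classSlug <- function(x) {
  gsub("[^a-z0-9_]+", "_", gsub("[()]", "_", gsub(",", "_", x)))
}

#' Generate a full synthetic dataset on disk
#'
#' Writes one 16-bit grayscale TIFF per channel per field of view, a manifest
#' TSV (+ channel-layout JSON sidecar), a ground-truth label TSV
#' (image_id, class) and a ground-truth center TSV (image_id, field_index,
#' row, col). The same seed regenerates the dataset byte-identically. The
#' ground truth is written alongside the manifest but is never read by any
#' training code path.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param dir output directory (created if needed).
#' @return A list with the \code{manifest} (\linkS4class{DatasetManifest}),
#'   \code{labels} and \code{centers} data.frames, and the file paths.
#' @export
generateDataset <- function(spec, dir) {
  stopifnot(is(spec, "SyntheticSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec@seed)
  rows <- NULL
  labels <- NULL
  centers <- NULL
  layout <- NULL
  for (cls in spec@patternClasses) {
    for (i in seq_len(spec@imagesPerClass)) {
      imageId <- sprintf("img_%s_%03d", .classSlug(cls), i)
      img <- generateImage(imageId, cls, spec)
      layout <- img@layout
      chn <- channelNames(layout)
      for (fi in seq_along(img@fields)) {
        paths <- character(length(chn))
        for (z in seq_along(chn)) {
          fn <- sprintf("%s_f%d_%s.tif", imageId, fi - 1L, chn[z])
          # fixed linear scale so relative per-image intensity survives
          px <- pmin(img@fields[[fi]][, , z] / 2, 1)
          tiff::writeTIFF(px, file.path(dir, fn), bits.per.sample = 16L)
          paths[z] <- fn
        }
        row <- data.frame(image_id = imageId, field_index = fi - 1L,
                          stringsAsFactors = FALSE)
        for (z in seq_along(chn)) row[[paste0("path_", chn[z])]] <- paths[z]
        row$label <- cls
        rows <- rbind(rows, row)
      }
      labels <- rbind(labels,
                      data.frame(image_id = imageId, class = cls,
                                 stringsAsFactors = FALSE))
      ctr <- img@metadata$centers
      if (!is.null(ctr) && nrow(ctr)) {
        ctr <- cbind(data.frame(image_id = imageId), ctr)
        centers <- rbind(centers, ctr)
      }
    }
  }
  if (is.null(layout)) {  # degenerate: zero images
    layout <- if (spec@structuralChannels == 1L)
      ChannelLayout(c("marker", "protein"), 1, 2) else
        ChannelLayout(c("nucleus", "body", "protein"), 1:2, 3)
    rows <- data.frame(image_id = character(), field_index = integer())
    for (cn in channelNames(layout)) rows[[paste0("path_", cn)]] <- character()
    rows$label <- character()
    labels <- data.frame(image_id = character(), class = character())
    centers <- data.frame(image_id = character(), field_index = integer(),
                          row = numeric(), col = numeric())
  }
  manifestPath <- file.path(dir, "manifest.tsv")
  manifest <- new("DatasetManifest", rows = rows, layout = layout)
  writeManifest(manifest, manifestPath)
  labelsPath <- file.path(dir, "labels.tsv")
  utils::write.table(labels, labelsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  centersPath <- file.path(dir, "centers.tsv")
  utils::write.table(centers, centersPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(manifest = readManifest(manifestPath),
       labels = labels, centers = centers,
       manifestPath = manifestPath, labelsPath = labelsPath,
       centersPath = centersPath, dir = dir)
}
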