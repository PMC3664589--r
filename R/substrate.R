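# Substrate construction: presets, crystalline band layout, the 6x6 chain
# lattice of an elementary fibril, and census/snapshot methods.

# run code under a temporary RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Substrate presets
#'
#' Named presets for model cellulosic substrates, characterized by chain
#' degree-of-polymerization range, crystallinity-index range and number of
#' microfibrils. Shipped presets: `avicel` (DP 250-300, CrI 0.5-0.6, 5
#' microfibrils), `filter_paper` (DP 700-800, CrI 0.4-0.5, 4),
#' `bacterial_cellulose` (DP 1800-2000, CrI 0.85-0.95, 2) and `cotton`
#' (DP 2500-3000, CrI 0.85-0.95, 2). All presets target at least one million
#' glucose units in the realized assembly. The table is stored as plain text
#' in `inst/extdata/substrate_presets.tsv`.
#'
#' @param name preset name (case-insensitive).
#' @return a [SubstratePreset-class].
#' @examples
#' substratePreset("avicel")
#' @export
substratePreset <- function(name) {
  tab <- read.delim(system.file("extdata", "substrate_presets.tsv",
                                package = "cellulosim"),
                    stringsAsFactors = FALSE)
  i <- match(tolower(name), tab$name)
  if (is.na(i))
    stop("unknown substrate preset '", name, "'; available: ",
         paste(tab$name, collapse = ", "))
  new("SubstratePreset", name = tab$name[i],
      dpRange = c(tab$dp_min[i], tab$dp_max[i]),
      criRange = c(tab$cri_min[i], tab$cri_max[i]),
      nMicrofibrils = as.integer(tab$n_microfibrils[i]),
      minTotal = as.numeric(tab$min_total[i]))
}

# crystalline/amorphous banding of one elementary fibril.
# Crystalline regions occur as transverse bands nominally `bandLength` units
# long; both chain ends always lie inside crystalline bands, so short or
# weakly crystalline chains get (possibly truncated) end bands. Returns a
# logical mask of length dp with exactly K crystalline units.
makeBandMask <- function(dp, K, bandLength = 200) {
  if (K >= dp) return(rep(TRUE, dp))
  if (K < 2)
    stop("infeasible crystallinity for DP ", dp,
         ": both fibril ends must lie in crystalline bands, so at least 2 ",
         "crystalline units are required (got ", K, ")")
  A <- dp - K
  nb <- max(2L, as.integer(round(K / bandLength)))
  if (nb - 1L > A) {
    nb <- A + 1L
    warning("crystallinity target too dense for DP ", dp,
            ": reduced crystalline band count to ", nb)
  }
  if (nb > K) nb <- as.integer(K)
  sizes <- rep(K %/% nb, nb)
  extra <- K %% nb
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes <- sizes[sample.int(nb)]
  ngap <- nb - 1L
  gaps <- if (ngap == 1L) A else
    diff(c(0L, sort(sample.int(A - 1L, ngap - 1L)), A))
  mask <- logical(dp)
  pos <- 1L
  for (b in seq_len(nb)) {
    mask[pos:(pos + sizes[b] - 1L)] <- TRUE
    pos <- pos + sizes[b]
    if (b <= ngap) pos <- pos + gaps[b]
  }
  stopifnot(sum(mask) == K, mask[1L], mask[dp])
  mask
}

# chain lattice of a 6x6 elementary fibril cross-section: depth (ring index),
# the covering chain one layer out (whose removal exposes this chain), and
# the face directions of surface chains.
efLattice <- function() {
  g <- expand.grid(chainCol = 0:5, chainRow = 0:5)  # local index = row*6+col
  g <- g[order(g$chainRow, g$chainCol), ]
  r <- g$chainRow; cc <- g$chainCol
  depth <- pmin(r, cc, 5 - r, 5 - cc)
  cover <- rep(NA_integer_, 36)
  for (k in seq_len(36)) {
    d <- depth[k]
    if (d == 0) next
    if (r[k] == d) p <- c(r[k] - 1, cc[k])
    else if (r[k] == 5 - d) p <- c(r[k] + 1, cc[k])
    else if (cc[k] == d) p <- c(r[k], cc[k] - 1)
    else p <- c(r[k], cc[k] + 1)
    cover[k] <- p[1] * 6 + p[2] + 1  # 1-based local index of covering chain
  }
  below <- rep(NA_integer_, 36)
  below[cover[!is.na(cover)]] <- which(!is.na(cover))
  list(chainRow = r, chainCol = cc, depth = depth, cover = cover,
       below = below,
       faceN = r == 0, faceS = r == 5, faceW = cc == 0, faceE = cc == 5)
}

#' Build an in-silico cellulose assembly
#'
#' Constructs microfibrils of elementary fibrils according to a preset or to
#' explicit structural ranges. Each microfibril draws a shared chain length
#' (DP) uniformly from `dpRange` and an elementary-fibril grid with 4-6 rows
#' and columns; every elementary fibril draws a crystallinity target uniformly
#' from `criRange` and lays crystalline bands (nominally 200 units) so that
#' both chain ends are crystalline and the realized crystallinity index falls
#' inside `criRange`. Builds are deterministic for a fixed seed.
#'
#' @param preset a [SubstratePreset-class] or preset name; `NULL` to build
#'   from the explicit arguments.
#' @param dpRange,criRange,nMicrofibrils,minTotal override the corresponding
#'   preset fields (`minTotal = NA` disables the total-size constraint, e.g.
#'   for single-microfibril scaled-down runs).
#' @param seed integer RNG seed.
#' @param maxTries redraw attempts when `minTotal` is not met.
#' @return a [CelluloseAssembly-class].
#' @examples
#' toy <- buildSubstrate(dpRange = c(40, 40), criRange = c(0.5, 0.6),
#'                       nMicrofibrils = 1, seed = 1)
#' crystallinityIndex(toy)
#' @export
buildSubstrate <- function(preset = NULL, dpRange = NULL, criRange = NULL,
                           nMicrofibrils = NULL, minTotal = NULL, seed = 1L,
                           maxTries = 50L) {
  if (is.character(preset)) preset <- substratePreset(preset)
  if (!is.null(preset)) {
    if (is.null(dpRange)) dpRange <- preset@dpRange
    if (is.null(criRange)) criRange <- preset@criRange
    if (is.null(nMicrofibrils)) nMicrofibrils <- preset@nMicrofibrils
    if (is.null(minTotal)) minTotal <- preset@minTotal
  }
  if (is.null(minTotal)) minTotal <- NA_real_
  stopifnot(length(dpRange) == 2, all(dpRange >= 7),
            length(criRange) == 2, all(criRange > 0), all(criRange <= 1),
            nMicrofibrils >= 1)
  nMf <- as.integer(nMicrofibrils)
  withSeed(seed, {
    for (try in seq_len(maxTries)) {
      dps <- dpRange[1]:dpRange[2]
      mfDp <- dps[sample.int(length(dps), nMf, replace = TRUE)]
      mfRows <- sample(4:6, nMf, replace = TRUE)
      mfCols <- sample(4:6, nMf, replace = TRUE)
      total <- sum(mfRows * mfCols * 36 * mfDp)
      if (is.na(minTotal) || total >= minTotal) break
      if (try == maxTries)
        stop("could not reach ", minTotal, " glucose units in ", maxTries,
             " draws; increase nMicrofibrils or relax minTotal")
    }
    lat <- efLattice()
    chainList <- vector("list", nMf)
    crysList <- vector("list", nMf)
    efCounter <- 0L
    chainCounter <- 0L
    uidCounter <- 0
    for (j in seq_len(nMf)) {
      dp <- mfDp[j]
      grid <- expand.grid(efCol = 0:(mfCols[j] - 1), efRow = 0:(mfRows[j] - 1))
      grid <- grid[order(grid$efRow, grid$efCol), ]
      nEf <- nrow(grid)
      Klo <- ceiling(criRange[1] * dp)
      Khi <- floor(criRange[2] * dp)
      efTabs <- vector("list", nEf)
      efMasks <- vector("list", nEf)
      for (e in seq_len(nEf)) {
        K <- round(runif(1, criRange[1], criRange[2]) * dp)
        if (Klo <= Khi) K <- min(max(K, Klo), Khi)
        mask <- makeBandMask(dp, K)
        outward <- c(N = grid$efRow[e] == 0, S = grid$efRow[e] == mfRows[j] - 1,
                     W = grid$efCol[e] == 0, E = grid$efCol[e] == mfCols[j] - 1)
        mfSurf <- lat$depth == 0 &
          ((lat$faceN & outward["N"]) | (lat$faceS & outward["S"]) |
           (lat$faceW & outward["W"]) | (lat$faceE & outward["E"]))
        below <- ifelse(is.na(lat$below), -1L,
                        chainCounter + lat$below - 1L)
        efTabs[[e]] <- data.frame(
          mf = j, ef = efCounter + e,
          efRow = grid$efRow[e], efCol = grid$efCol[e],
          chainRow = lat$chainRow, chainCol = lat$chainCol,
          depth = lat$depth, below = below,
          mfSurface = as.integer(mfSurf), dp = dp,
          startUid = uidCounter + (seq_len(36) - 1) * dp)
        efMasks[[e]] <- mask
        chainCounter <- chainCounter + 36L
        uidCounter <- uidCounter + 36 * dp
      }
      efCounter <- efCounter + nEf
      chainList[[j]] <- do.call(rbind, efTabs)
      crysList[[j]] <- as.raw(unlist(lapply(efMasks, rep, times = 36)))
    }
    chains <- do.call(rbind, chainList)
    rownames(chains) <- NULL
    crystalline <- do.call(c, crysList)
    gSim <- sum(chains$dp)
    assembly <- new("CelluloseAssembly", chains = chains,
                    crystalline = crystalline, gSim = as.numeric(gSim),
                    nMicrofibrils = nMf, solublePool = numeric(6),
                    meta = list(
                      preset = if (is.null(preset)) NA_character_ else preset@name,
                      seed = seed, dpRange = dpRange, criRange = criRange,
                      mfDp = mfDp, mfRows = mfRows, mfCols = mfCols,
                      realizedCri = sum(as.integer(crystalline)) / gSim))
    validObject(assembly)
    assembly
  })
}

#' Build a small fully specified toy assembly
#'
#' Deterministic single-microfibril assembly for tests and oracle
#' computations: an `efRows` x `efCols` grid of elementary fibrils, all
#' chains of length `dp`, with an explicit crystalline band layout.
#'
#' @param dp chain length.
#' @param efRows,efCols elementary-fibril grid dimensions.
#' @param bands `NULL` for fully amorphous, `TRUE` for fully crystalline, or
#'   a two-column matrix of half-open `[start, end)` 0-based axial intervals
#'   applied to every elementary fibril.
#' @param maxUnits guard against non-toy sizes (exhaustive oracles only).
#' @return a [CelluloseAssembly-class].
#' @examples
#' toy <- makeToyAssembly(dp = 400, bands = cbind(100, 300))
#' crystallinityIndex(toy)  # 0.5
#' @export
makeToyAssembly <- function(dp, efRows = 1L, efCols = 1L, bands = NULL,
                            maxUnits = 20000L) {
  nUnits <- efRows * efCols * 36 * dp
  if (nUnits > maxUnits)
    stop("toy assembly would have ", nUnits, " units; exceeds the ",
         maxUnits, "-unit exhaustive-oracle limit")
  mask <- logical(dp)
  if (isTRUE(bands)) mask[] <- TRUE
  else if (!is.null(bands)) {
    for (k in seq_len(nrow(bands)))
      mask[(bands[k, 1] + 1):bands[k, 2]] <- TRUE
  }
  lat <- efLattice()
  grid <- expand.grid(efCol = 0:(efCols - 1), efRow = 0:(efRows - 1))
  grid <- grid[order(grid$efRow, grid$efCol), ]
  tabs <- vector("list", nrow(grid))
  chainCounter <- 0L
  uidCounter <- 0
  for (e in seq_len(nrow(grid))) {
    outward <- c(N = grid$efRow[e] == 0, S = grid$efRow[e] == efRows - 1,
                 W = grid$efCol[e] == 0, E = grid$efCol[e] == efCols - 1)
    mfSurf <- lat$depth == 0 &
      ((lat$faceN & outward["N"]) | (lat$faceS & outward["S"]) |
       (lat$faceW & outward["W"]) | (lat$faceE & outward["E"]))
    tabs[[e]] <- data.frame(
      mf = 1L, ef = e, efRow = grid$efRow[e], efCol = grid$efCol[e],
      chainRow = lat$chainRow, chainCol = lat$chainCol, depth = lat$depth,
      below = ifelse(is.na(lat$below), -1L, chainCounter + lat$below - 1L),
      mfSurface = as.integer(mfSurf), dp = dp,
      startUid = uidCounter + (seq_len(36) - 1) * dp)
    chainCounter <- chainCounter + 36L
    uidCounter <- uidCounter + 36 * dp
  }
  chains <- do.call(rbind, tabs)
  rownames(chains) <- NULL
  assembly <- new("CelluloseAssembly", chains = chains,
                  crystalline = as.raw(rep(mask, nrow(grid) * 36)),
                  gSim = as.numeric(nUnits), nMicrofibrils = 1L,
                  solublePool = numeric(6),
                  meta = list(preset = "toy", seed = NA_integer_,
                              dpRange = c(dp, dp),
                              criRange = rep(mean(mask), 2),
                              realizedCri = mean(mask)))
  validObject(assembly)
  assembly
}

#' @describeIn crystallinityIndex time-zero crystallinity of an assembly.
#' @export
setMethod("crystallinityIndex", "CelluloseAssembly", function(x, ...) {
  insol <- x@gSim  # freshly built assemblies have no solubilized units
  if (insol <= 0) {
    warning("no insoluble cellulose: crystallinity index undefined")
    return(NA_real_)
  }
  sum(as.integer(x@crystalline)) / insol
})

#' @describeIn chainEndFraction intact-substrate end fraction (one end of
#'   each polarity per chain).
#' @export
setMethod("chainEndFraction", "CelluloseAssembly",
  function(x, polarity = "reducing", ...) {
    polarity <- match.arg(polarity, c("reducing", "nonreducing"))
    100 * nrow(x@chains) / x@gSim
  })

#' @describeIn surfaceCensus time-zero census of an assembly.
#' @export
setMethod("surfaceCensus", "CelluloseAssembly", function(x, ...) {
  ch <- x@chains
  nS <- vapply(seq_len(x@nMicrofibrils), function(j)
    sum(ch$dp[ch$mf == j & ch$depth == 0]), numeric(1))
  nChainsMf <- vapply(seq_len(x@nMicrofibrils), function(j)
    sum(ch$mf == j), numeric(1))
  data.frame(mf = seq_len(x@nMicrofibrils), nS = nS, nR = nChainsMf,
             nNR = nChainsMf, nSL = rep(sum(x@solublePool), x@nMicrofibrils) *
               (seq_len(x@nMicrofibrils) == 1))
})

#' @describeIn glucoseCount total units of an assembly.
#' @export
setMethod("glucoseCount", "CelluloseAssembly", function(x) x@gSim)

# expand chain-level table to unit-level location columns
unitFrame <- function(chains) {
  n <- sum(chains$dp)
  idx <- rep(seq_len(nrow(chains)), chains$dp)
  axial <- sequence(chains$dp) - 1L
  data.frame(uid = seq_len(n) - 1L, mf = chains$mf[idx], ef = chains$ef[idx],
             efRow = chains$efRow[idx], efCol = chains$efCol[idx],
             chain = idx - 1L, chainRow = chains$chainRow[idx],
             chainCol = chains$chainCol[idx], depth = chains$depth[idx],
             axial = axial, dp = chains$dp[idx],
             mfSurface = chains$mfSurface[idx] == 1)
}

#' @describeIn substrateSnapshot time-zero snapshot.
#' @export
setMethod("substrateSnapshot", "CelluloseAssembly", function(x, ...) {
  u <- unitFrame(x@chains)
  u$endState <- ifelse(u$axial == 0L, 1L, ifelse(u$axial == u$dp - 1L, -1L, 0L))
  u$efSurface <- u$depth == 0L
  u$crystalline <- as.integer(x@crystalline) == 1L
  u$soluble <- FALSE
  u$distanceNR <- u$dp - 1L - u$axial
  u$blocked <- FALSE
  u$dp <- NULL
  u
})

#' Write a substrate snapshot to a columnar text file
#'
#' @param x a `CelluloseAssembly` or `HydrolysisResult`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeSnapshot <- function(x, path) {
  write.csv(substrateSnapshot(x), path, row.names = FALSE)
  invisible(path)
}

#' @describeIn chainLengthDistribution intact assembly: one bin per distinct
#'   chain DP plus any seeded soluble pool.
#' @export
setMethod("chainLengthDistribution", "CelluloseAssembly", function(x, ...) {
  tab <- table(x@chains$dp)
  ins <- data.frame(dp = as.integer(names(tab)), count = as.numeric(tab),
                    phase = "insoluble")
  sol <- data.frame(dp = 1:6, count = x@solublePool, phase = "soluble")
  out <- rbind(ins, sol[sol$count > 0, ])
  out[order(out$dp), ]
})

setMethod("show", "CelluloseAssembly", function(object) {
  cat("CelluloseAssembly:", object@nMicrofibrils, "microfibril(s),",
      nrow(object@chains) / 36, "elementary fibrils,",
      format(object@gSim, big.mark = ","), "glucose units\n")
  cat("  DP range:", paste(range(object@chains$dp), collapse = "-"),
      " realized CrI:", signif(object@meta$realizedCri, 4), "\n")
  if (!is.null(object@meta$preset) && !is.na(object@meta$preset))
    cat("  preset:", object@meta$preset, " seed:", object@meta$seed, "\n")
  invisible(NULL)
})
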