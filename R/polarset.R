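#' Validate a plain polar set on a sequence
#'
#' A polar set of slackness s requires every two member-k-mer occurrences
#' (including two occurrences of the same k-mer) to lie at least
#' \code{(1 - s) * w} bases apart; the threshold is rounded up to
#' \code{ceiling((1 - s) * w)} and the comparison is inclusive. Every
#' window then contains at most one member occurrence when s < 1/2.
#'
#' @inheritParams selectMinimizers
#' @param kmers character vector of member k-mers.
#' @param w window size in k-mers.
#' @param s slackness in [0, 1/2).
#' @return List with \code{valid} (logical), \code{violations} (data.frame
#'   of offending position pairs, 1-based) and \code{threshold}.
#' @export
validatePolar <- function(x, kmers, w, s = 0.4) {
  .checkSlackness(s)
  kmers <- as.character(kmers)
  if (length(kmers) == 0)
    return(list(valid = TRUE, violations = .emptyViolations(),
                threshold = .spacingThreshold(w, s)))
  k <- nchar(kmers[1])
  .checkWK(w, k)
  thr <- .spacingThreshold(w, s)
  occ <- .kmerOccurrences(x, kmers, k)
  v <- .adjacentViolations(occ, thr)
  list(valid = nrow(v) == 0, violations = v, threshold = thr)
}

.emptyViolations <- function() {
  data.frame(layer = integer(0), pos = integer(0), otherPos = integer(0),
             gap = integer(0), kmer = character(0), otherKmer = character(0))
}

# occurrence table of a k-mer set: pos (1-based, sorted), kmer, layer
.kmerOccurrences <- function(x, kmers, k, layerIds = NULL) {
  codes <- .seqCodes(x)
  res <- cpp_find_kmer_occurrences(codes, as.integer(k), kmers)
  occ <- data.frame(pos = res$pos + 1L, kmer = kmers[res$kmer],
                    layer = if (is.null(layerIds)) 1L else layerIds[res$kmer])
  occ[order(occ$pos), , drop = FALSE]
}

.adjacentViolations <- function(occ, thr, layer = 1L) {
  if (nrow(occ) < 2) return(.emptyViolations())
  gap <- diff(occ$pos)
  bad <- which(gap < thr)
  data.frame(layer = rep.int(layer, length(bad)), pos = occ$pos[bad],
             otherPos = occ$pos[bad + 1L], gap = gap[bad],
             kmer = occ$kmer[bad], otherKmer = occ$kmer[bad + 1L])
}

#' Validate a layered polar set on a sequence
#'
#' Checks the layered condition for every occurrence t of every member of
#' layer j: either t lies at least \code{ceiling((1 - s) * w)} bases from
#' every occurrence of every k-mer in layers 1..j, or t is \emph{covered} -
#' two occurrences of k-mers from layers 1..j-1 flank it strictly
#' (l < t < h) at most w bases apart. A single layer degenerates to
#' \code{\link{validatePolar}}.
#'
#' @inheritParams selectMinimizers
#' @param lps a \linkS4class{LayeredPolarSet}.
#' @return List with \code{valid}, \code{violations} and \code{threshold}.
#' @export
validateLayered <- function(x, lps) {
  stopifnot(is(lps, "LayeredPolarSet"))
  occ <- .layeredOccurrences(x, lps)
  thr <- spacingThreshold(lps)
  w <- lps@w
  viol <- .emptyViolations()
  for (j in seq_along(lps@layers)) {
    here <- occ[occ$layer == j, , drop = FALSE]
    if (nrow(here) == 0) next
    upto <- occ[occ$layer <= j, , drop = FALSE]   # condition 1 pool
    prev <- occ$pos[occ$layer < j]                # condition 2 pool
    cov <- .coveredFlags(here$pos, prev, w)
    un <- which(!cov)
    if (length(un) == 0) next
    ii <- match(here$pos[un], upto$pos)
    gapL <- here$pos[un] - c(-Inf, upto$pos)[ii]          # left neighbour
    gapR <- c(upto$pos, Inf)[ii + 1L] - here$pos[un]      # right neighbour
    for (q in seq_along(un)) {
      t <- here$pos[un[q]]
      if (gapL[q] < thr) {
        other <- upto[ii[q] - 1L, ]
        viol <- rbind(viol, data.frame(layer = j, pos = t,
                                       otherPos = other$pos, gap = gapL[q],
                                       kmer = here$kmer[un[q]],
                                       otherKmer = other$kmer))
      }
      if (gapR[q] < thr) {
        other <- upto[ii[q] + 1L, ]
        viol <- rbind(viol, data.frame(layer = j, pos = t,
                                       otherPos = other$pos, gap = gapR[q],
                                       kmer = here$kmer[un[q]],
                                       otherKmer = other$kmer))
      }
    }
  }
  rownames(viol) <- NULL
  list(valid = nrow(viol) == 0, violations = viol, threshold = thr)
}

.layeredOccurrences <- function(x, lps) {
  km <- unlist(lps@layers, use.names = FALSE)
  ids <- rep.int(seq_along(lps@layers), lengths(lps@layers))
  if (length(km) == 0)
    return(data.frame(pos = integer(0), kmer = character(0),
                      layer = integer(0)))
  .kmerOccurrences(x, km, lps@k, ids)
}

# covered: exist prev occurrences l < t < h with h - l <= w (nearest
# flankers minimise h - l, so they decide)
.coveredFlags <- function(pos, prevPos, w) {
  if (length(prevPos) == 0) return(rep(FALSE, length(pos)))
  prevPos <- sort(prevPos)
  li <- findInterval(pos - 1L, prevPos)        # index of largest < t
  hi <- findInterval(pos, prevPos) + 1L        # index of smallest > t
  l <- ifelse(li >= 1L, prevPos[pmax(li, 1L)], NA_integer_)
  h <- ifelse(hi <= length(prevPos), prevPos[pmin(hi, length(prevPos))],
              NA_integer_)
  !is.na(l) & !is.na(h) & (h - l <= w)
}

#' Link energy of a (layered) polar set on a sequence
#'
#' Enumerates the uncovered member occurrences in position order;
#' consecutive ones at most w bases apart form links of energy
#' 2l/(w+1) - 1. The total is also derived from covered-context
#' bookkeeping, L = 2*Acov/(w+1) - Aele - Aseg, and the two routes are
#' verified to agree exactly (both are computed over a common integer
#' numerator). Acov counts, for each uncovered occurrence p, the context
#' start positions p - w .. p as an interval union, so the identity holds
#' regardless of where occurrences sit relative to fragment ends.
#'
#' @inheritParams validateLayered
#' @param validate check the layered polar condition first and fail on
#'   violations (default TRUE).
#' @return A \linkS4class{LinkStats}.
#' @examples
#' # three polar k-mers at gaps 3 and 4 with w = 5: energies 0 and 1/3
#' s <- simulateSequence("uniform", n = 60, seed = 7)
#' @export
linkEnergy <- function(x, lps, validate = TRUE) {
  stopifnot(is(lps, "LayeredPolarSet"))
  if (validate) {
    v <- validateLayered(x, lps)
    if (!v$valid)
      stop("invalid layered polar set: ", nrow(v$violations),
           " spacing violation(s); first at positions ",
           v$violations$pos[1], "/", v$violations$otherPos[1],
           " (gap ", v$violations$gap[1], " < ", v$threshold, ")")
  }
  occ <- .layeredOccurrences(x, lps)
  w <- lps@w
  cov <- rep(FALSE, nrow(occ))
  for (j in seq_along(lps@layers)) {
    sel <- occ$layer == j
    if (!any(sel)) next
    cov[sel] <- .coveredFlags(occ$pos[sel], occ$pos[occ$layer < j], w)
  }
  elements <- occ$pos[!cov]
  .linkStatsFromElements(elements, w)
}

# pairwise links and covered-context bookkeeping from sorted uncovered
# element positions; exact integer-numerator equality check
.linkStatsFromElements <- function(elements, w) {
  elements <- sort(as.integer(elements))
  m <- length(elements)
  if (m == 0) {
    return(new("LinkStats", acov = 0, aele = 0, aseg = 0, total = 0,
               links = data.frame(left = integer(0), right = integer(0),
                                  gap = integer(0), energy = numeric(0)),
               elements = integer(0), w = as.integer(w)))
  }
  gap <- diff(elements)
  linked <- gap <= w
  links <- data.frame(left = elements[c(linked, FALSE)],
                      right = elements[c(FALSE, linked)],
                      gap = gap[linked],
                      energy = (2 * gap[linked] - (w + 1)) / (w + 1))
  acov <- as.numeric((w + 1) + sum(pmin(gap, w + 1)))
  aele <- as.numeric(m)
  aseg <- as.numeric(1 + sum(!linked))
  num_pair <- sum(2 * gap[linked] - (w + 1))
  num_formula <- 2 * acov - (w + 1) * (aele + aseg)
  if (num_pair != num_formula)
    stop("internal error: link-energy formulas disagree (",
         num_pair, " vs ", num_formula, ")")
  new("LinkStats", acov = acov, aele = aele, aseg = aseg,
      total = num_formula / (w + 1), links = links,
      elements = elements, w = as.integer(w))
}

#' Bounds on the expected number of selected positions
#'
#' For a valid (layered) polar set with slackness s < 1/2 and any
#' compatible order, the expected number of positions selected lies
#' between 1 + E0 - X - L and 1 + E0 + D - L per fragment. The bounds
#' returned here resolve fragment-end effects exactly rather than
#' asymptotically: the covered-context count is clipped to contexts that
#' actually exist, a segment's entering/trailing charged context is only
#' counted when it exists, and link charges whose context existence
#' depends on the order (linked element pairs inside the first or last
#' window of a fragment) widen the interval by one count each. Away from
#' fragment ends this reduces exactly to the link-energy formula.
#'
#' @inheritParams validateLayered
#' @param profile optional precomputed \linkS4class{EnergyProfile}.
#' @param linkStats optional precomputed \linkS4class{LinkStats}.
#' @return List with \code{count} (named lower/upper expected selected
#'   count), \code{densityFactor} (the same bounds scaled by
#'   (w + 1)/nKmers) and the components \code{E0}, \code{D}, \code{X},
#'   \code{L} (the uncorrected link energy).
#' @export
densityBounds <- function(x, lps, profile = NULL, linkStats = NULL) {
  stopifnot(is(lps, "LayeredPolarSet"))
  .checkSlackness(lps@s)
  if (is.null(profile)) profile <- energyProfile(x, lps@w, lps@k)
  if (is.null(linkStats)) linkStats <- linkEnergy(x, lps)
  E0 <- profile@e0; D <- profile@deficit; X <- profile@surplus
  w <- lps@w
  bc <- .boundaryCharges(linkStats@elements, w,
                         .fragmentRanges(.seqCodes(x), lps@k))
  base <- profile@nFragments
  fixed <- base + 2 * bc$acov / (w + 1) * (-1) + bc$entering + bc$trailing
  count <- c(lower = fixed + E0 - X + bc$linkMin,
             upper = fixed + E0 + D + bc$linkMax)
  list(count = count,
       densityFactor = count * (lps@w + 1) / profile@nKmers,
       E0 = E0, D = D, X = X, L = linkStats@total,
       nKmers = profile@nKmers, nFragments = base)
}

.fragmentRanges <- function(codes, k) {
  valid <- cpp_valid_starts(codes, as.integer(k))
  r <- rle(as.vector(valid))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(a = starts[r$values], b = ends[r$values])  # 1-based k-mer runs
}

# Exact per-fragment charge bookkeeping for the density bounds. Elements
# (sorted, 1-based) split into segments at gaps > w; per segment, the
# entering charge exists when the first element has a full window before
# it, the trailing charge when the last element's own context exists; a
# linked pair charges at either of two contexts (which one depends on the
# order) so a pair with only one existing context contributes to the upper
# bound only.
.boundaryCharges <- function(elements, w, frag) {
  out <- list(acov = 0, entering = 0, trailing = 0, linkMin = 0, linkMax = 0)
  if (length(elements) == 0) return(out)
  fi <- findInterval(elements, frag$a)
  for (f in unique(fi)) {
    a <- frag$a[f]; lastctx <- frag$b[f] - w
    e <- elements[fi == f]
    gap <- if (length(e) > 1) diff(e) else integer(0)
    segFirst <- c(TRUE, gap > w)
    firsts <- e[segFirst]
    lasts <- e[c(segFirst[-1], TRUE)]
    out$entering <- out$entering + sum(firsts >= a + w)
    out$trailing <- out$trailing + sum(lasts <= lastctx)
    linked <- which(gap <= w)
    if (length(linked) > 0) {
      ex1 <- e[linked + 1L] >= a + w      # context at (right - w)
      ex2 <- e[linked] <= lastctx         # context at left
      out$linkMin <- out$linkMin + sum(ex1 & ex2)
      out$linkMax <- out$linkMax + sum(ex1 | ex2)
    }
    lo <- pmax(firsts - w, a)
    hi <- pmin(lasts, lastctx)
    out$acov <- out$acov + sum(pmax(hi - lo + 1, 0))
  }
  out
}

#' @describeIn LayeredPolarSet-class the layer list.
#' @param x a \linkS4class{LayeredPolarSet}.
#' @export
setMethod("layers", "LayeredPolarSet", function(x) x@layers)

#' @describeIn LayeredPolarSet-class slackness s.
#' @export
setMethod("slackness", "LayeredPolarSet", function(x) x@s)

#' @describeIn LayeredPolarSet-class window size.
#' @export
setMethod("windowSize", "LayeredPolarSet", function(x) x@w)

#' @describeIn LayeredPolarSet-class k-mer length.
#' @export
setMethod("kmerSize", "LayeredPolarSet", function(x) x@k)

#' @describeIn LayeredPolarSet-class minimal member spacing
#'   \code{ceiling((1 - s) * w)}.
#' @export
setMethod("spacingThreshold", "LayeredPolarSet",
          function(x) .spacingThreshold(x@w, x@s))

setMethod("show", "LayeredPolarSet", function(object) {
  cat("LayeredPolarSet (w =", object@w, ", k =", object@k,
      ", s =", object@s, ")\n")
  cat("  ", length(object@layers), "layer(s), sizes:",
      paste(lengths(object@layers), collapse = ", "), "\n")
  cat("  spacing threshold:", spacingThreshold(object), "bases\n")
  if (!is.null(object@metadata$log))
    cat("  built in", nrow(object@metadata$log), "round(s); final L =",
        format(tail(object@metadata$log$L, 1)), "\n")
})

#' @describeIn LinkStats-class total link energy L.
#' @param x a \linkS4class{LinkStats}.
#' @export
setMethod("totalLinkEnergy", "LinkStats", function(x) x@total)

#' @describeIn LinkStats-class per-link table (left, right, gap, energy).
#' @export
setMethod("linkTable", "LinkStats", function(x) x@links)

#' @describeIn LinkStats-class sorted uncovered member occurrences.
#' @export
setMethod("uncoveredElements", "LinkStats", function(x) x@elements)

setMethod("show", "LinkStats", function(object) {
  cat("LinkStats (w =", object@w, ")\n")
  cat("  elements (uncovered occurrences):", object@aele,
      " links:", nrow(object@links), "\n")
  cat("  Acov =", object@acov, " Aele =", object@aele,
      " Aseg =", object@aseg, "\n")
  cat(sprintf("  total link energy L = %.6g\n", object@total))
})

#' Write/read a layered k-mer set as TSV
#'
#' Two tab-separated columns, \code{kmer} and \code{layer} (1-based, lower
#' layer = higher priority). '#'-prefixed header lines carry w, k, s and
#' the construction seed so downstream runs can verify parameter
#' compatibility.
#'
#' @param lps a \linkS4class{LayeredPolarSet}.
#' @param path output / input file.
#' @return \code{readLayeredSet} returns a \linkS4class{LayeredPolarSet}.
#' @export
writeLayeredSet <- function(lps, path) {
  stopifnot(is(lps, "LayeredPolarSet"))
  seed <- lps@metadata$seed
  hdr <- c(sprintf("# w=%d", lps@w), sprintf("# k=%d", lps@k),
           sprintf("# s=%s", format(lps@s)),
           if (!is.null(seed)) sprintf("# seed=%d", as.integer(seed)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- data.frame(kmer = unlist(lps@layers, use.names = FALSE),
                   layer = rep.int(seq_along(lps@layers),
                                   lengths(lps@layers)))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeLayeredSet
#' @export
readLayeredSet <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getp <- function(name) {
    m <- regmatches(hdr, regexec(paste0("\\b", name, "=([0-9.eE+-]+)"), hdr))
    v <- unlist(lapply(m, function(z) if (length(z) == 2) z[2] else NULL))
    if (length(v) == 0) NULL else as.numeric(v[1])
  }
  w <- getp("w"); k <- getp("k"); s <- getp("s"); seed <- getp("seed")
  if (is.null(w) || is.null(k) || is.null(s))
    stop("layered set file lacks '# w=', '# k=' or '# s=' header lines")
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) {
    lay <- list()
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2))
      stop("malformed layered set file: expected 'kmer<TAB>layer' rows")
    km <- vapply(parts, `[`, character(1), 1L)
    id <- as.integer(vapply(parts, `[`, character(1), 2L))
    if (anyNA(id) || any(id < 1)) stop("malformed layer indices")
    lay <- lapply(seq_len(max(id)), function(j) km[id == j])
  }
  meta <- if (is.null(seed)) list() else list(seed = as.integer(seed))
  LayeredPolarSet(lay, w = w, k = k, s = s, metadata = meta)
}
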