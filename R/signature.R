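# 96-trinucleotide spectra, cosine comparison with signature catalogues,
# and hierarchical clustering.

#' Build a normalized 96-class spectrum from excess frequencies
#'
#' Negative class deltas (sampling noise) are clipped to zero and the
#' vector is normalized to sum 1. An input with no positive class is an
#' error rather than a 0/0 spectrum.
#'
#' @param deltas a [DeltaFrequencyTable] or a named numeric vector over the
#'   96 classes (order as [sub96Labels()]).
#' @param name spectrum label (defaults to the sample id).
#' @return a [Spectrum96].
#' @export
buildSpectrum <- function(deltas, name = NULL) {
  if (methods::is(deltas, "DeltaFrequencyTable")) {
    if (is.null(name)) name <- deltas@sample
    w <- deltas@delta96
  } else {
    w <- deltas
    if (is.null(name)) name <- "spectrum"
  }
  if (length(w) != 96) stop("96 class values required")
  if (!is.null(names(w))) {
    if (!setequal(names(w), SUB96)) stop("unknown class labels")
    w <- w[SUB96]
  } else names(w) <- SUB96
  w <- pmax(w, 0)
  if (sum(w) <= 0) stop("no positive signal in any class")
  methods::new("Spectrum96", name = name, weights = w / sum(w),
               normalized = TRUE)
}

setMethod("show", "Spectrum96", function(object) {
  cat("Spectrum96 '", object@name, "' (normalized: ", object@normalized,
      ")\n", sep = "")
  top <- sort(object@weights, decreasing = TRUE)[1:5]
  cat("  top classes:", paste(names(top), round(top, 3), collapse = ", "),
      "\n")
})

#' Spectrum weights
#' @param x a [Spectrum96] or [SpectrumSet].
#' @return named numeric vector (length 96) or a 96 x n matrix.
#' @export
spectrumWeights <- function(x) {
  if (methods::is(x, "SpectrumSet")) x@weights else x@weights
}

#' Cosine similarity of two spectra
#'
#' `dot(a, b) / (|a| |b|)`; invariant to positive rescaling of either
#' argument, in `[0, 1]` for non-negative spectra.
#'
#' @param a,b [Spectrum96] objects or numeric vectors of equal length.
#' @return the cosine similarity.
#' @export
cosineSimilarity <- function(a, b) {
  if (methods::is(a, "Spectrum96")) a <- a@weights
  if (methods::is(b, "Spectrum96")) b <- b@weights
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity of a zero vector")
  sum(a * b) / (na * nb)
}

#' Bundle spectra into a SpectrumSet
#' @param ... [Spectrum96] objects, lists of them, or [SpectrumSet]s.
#' @return a [SpectrumSet] with columns in input order.
#' @export
spectrumSet <- function(...) {
  items <- list(...)
  cols <- list()
  for (it in items) {
    if (methods::is(it, "SpectrumSet")) {
      for (j in seq_len(ncol(it@weights)))
        cols[[colnames(it@weights)[j]]] <- it@weights[, j]
    } else if (methods::is(it, "Spectrum96")) {
      cols[[it@name]] <- it@weights
    } else if (is.list(it)) {
      for (sp in it) cols[[sp@name]] <- sp@weights
    } else stop("unsupported input")
  }
  m <- do.call(cbind, cols)
  rownames(m) <- SUB96
  methods::new("SpectrumSet", weights = m)
}

setMethod("show", "SpectrumSet", function(object) {
  cat("SpectrumSet with", ncol(object@weights), "spectra\n")
})

setMethod("length", "SpectrumSet", function(x) ncol(x@weights))

.parseClassLabel <- function(lab) {
  lab <- toupper(trimws(lab))
  bracket <- grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", lab)
  arrow <- grepl("^[ACGT]{3}>[ACGT]{3}$", lab)
  out <- rep(NA_character_, length(lab))
  out[bracket] <- lab[bracket]
  if (any(arrow)) {
    from <- substr(lab[arrow], 1, 3)
    to <- substr(lab[arrow], 5, 7)
    ok <- substr(from, 1, 1) == substr(to, 1, 1) &
      substr(from, 3, 3) == substr(to, 3, 3) &
      substr(from, 2, 2) != substr(to, 2, 2)
    conv <- ifelse(ok, paste0(substr(from, 1, 1), "[", substr(from, 2, 2),
                              ">", substr(to, 2, 2), "]",
                              substr(from, 3, 3)), NA)
    out[arrow] <- conv
  }
  out
}

#' Load a 96-class signature catalogue from TSV
#'
#' Expects a header line and a first column of class labels in either the
#' bracket dialect (`A[C>A]A`) or the triplet-change dialect (`ACA>AAA`),
#' one column per signature. Rows may appear in any order; every class must
#' occur exactly once. Columns are normalized to sum 1.
#'
#' @param path TSV path.
#' @return a [SpectrumSet].
#' @export
loadSignatureCatalogue <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  lab <- .parseClassLabel(as.character(tab[[1]]))
  bad <- which(is.na(lab))
  if (length(bad))
    stop("unparseable class labels: ",
         paste(head(tab[[1]][bad], 5), collapse = ", "))
  dup <- unique(lab[duplicated(lab)])
  if (length(dup))
    stop("duplicate class labels: ", paste(head(dup, 5), collapse = ", "))
  missing <- setdiff(SUB96, lab)
  if (length(missing))
    stop("missing classes: ", paste(head(missing, 5), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("catalogue values must be numeric")
  rownames(m) <- lab
  m <- m[SUB96, , drop = FALSE]
  if (any(m < 0)) stop("catalogue weights must be non-negative")
  m <- sweep(m, 2, colSums(m), "/")
  methods::new("SpectrumSet", weights = m)
}

#' Pairwise cosine-distance matrix of a spectrum set
#' @param set a [SpectrumSet].
#' @return symmetric matrix of 1 - cosine distances.
#' @export
cosineDistances <- function(set) {
  m <- set@weights
  nrm <- sqrt(colSums(m^2))
  if (any(nrm == 0)) stop("zero spectrum in set")
  d <- 1 - crossprod(sweep(m, 2, nrm, "/"))
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Hierarchical clustering of spectra on cosine distance
#'
#' Agglomerative clustering with the chosen linkage on 1 - cosine
#' distances. Ties in the distance matrix are broken deterministically by
#' input order (hclust's behaviour).
#'
#' @param set a [SpectrumSet] with at least 2 spectra.
#' @param linkage "average" (default), "complete" or "single".
#' @return a [SpectrumClustering].
#' @export
clusterSpectra <- function(set, linkage = c("average", "complete",
                                            "single")) {
  linkage <- match.arg(linkage)
  if (ncol(set@weights) < 2) stop("at least 2 spectra required")
  d <- cosineDistances(set)
  tree <- hclust(as.dist(d), method = linkage)
  methods::new("SpectrumClustering", dist = d, tree = tree,
               linkage = linkage)
}

setMethod("show", "SpectrumClustering", function(object) {
  cat("SpectrumClustering of", nrow(object@dist), "spectra (",
      object@linkage, "linkage )\n")
})

#' Cluster assignments at a cut
#' @param clustering a [SpectrumClustering].
#' @param k number of clusters (or use `h`).
#' @param h cut height.
#' @return named integer vector of cluster memberships.
#' @export
cutSpectra <- function(clustering, k = NULL, h = NULL) {
  cutree(clustering@tree, k = k, h = h)
}

#' Does a set of samples join a target spectrum before any other member?
#'
#' Replays the merge sequence and finds the first cluster containing all of
#' `samples` together with `target`; returns TRUE when that cluster
#' contains none of `others`. Used to ask whether sample spectra form a
#' sub-cluster with one catalogue signature before any other catalogue
#' signature joins.
#'
#' @param clustering a [SpectrumClustering].
#' @param samples character vector of sample spectrum names.
#' @param target the catalogue signature of interest.
#' @param others other catalogue names (default: all remaining leaves).
#' @return logical scalar.
#' @export
joinsBefore <- function(clustering, samples, target, others = NULL) {
  tree <- clustering@tree
  labs <- tree$labels
  want <- match(c(samples, target), labs)
  if (anyNA(want)) stop("unknown spectrum name")
  if (is.null(others)) others <- setdiff(labs, c(samples, target))
  oth <- match(others, labs)
  members <- lapply(seq_along(labs), function(i) i)  # leaves
  clusters <- list()
  for (s in seq_len(nrow(tree$merge))) {
    get <- function(j) if (j < 0) -j else clusters[[j]]
    clusters[[s]] <- c(if (tree$merge[s, 1] < 0) -tree$merge[s, 1]
                       else clusters[[tree$merge[s, 1]]],
                       if (tree$merge[s, 2] < 0) -tree$merge[s, 2]
                       else clusters[[tree$merge[s, 2]]])
    if (all(want %in% clusters[[s]]))
      return(!any(oth %in% clusters[[s]]))
  }
  FALSE
}

#' Fraction of C-type weight with a 3' pyrimidine (NpCpY consensus)
#'
#' The context peak characteristic of alkylating-agent signatures: mutated
#' cytosines flanked 3' by C or T. Reported relative to the total weight of
#' the three C-rooted types.
#'
#' @param spectrum a [Spectrum96].
#' @return fraction in `[0, 1]` (NA if the spectrum has no C-type weight).
#' @export
npcyFraction <- function(spectrum) {
  w <- spectrum@weights
  ctype <- grepl("\\[C>", names(w))
  tot <- sum(w[ctype])
  if (tot == 0) return(NA_real_)
  y3 <- ctype & grepl("\\][CT]$", names(w))
  sum(w[y3]) / tot
}

#' Export a clustering as Newick
#' @param clustering a [SpectrumClustering].
#' @param path output path.
#' @export
writeNewick <- function(clustering, path) {
  ape::write.tree(ape::as.phylo(clustering@tree), file = path)
  invisible(path)
}

#' Write the linkage table of a clustering as TSV
#'
#' One row per merge: the two joined nodes (negative numbers are leaves,
#' positive numbers earlier merges, hclust convention) and the merge
#' height (cosine distance).
#'
#' @param clustering a [SpectrumClustering].
#' @param path output path.
#' @export
writeLinkageTable <- function(clustering, path) {
  tree <- clustering@tree
  write.table(data.frame(step = seq_len(nrow(tree$merge)),
                         node1 = tree$merge[, 1], node2 = tree$merge[, 2],
                         height = tree$height),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the pairwise cosine-similarity matrix as TSV
#' @param set a [SpectrumSet].
#' @param path output path.
#' @export
writeSimilarityMatrix <- function(set, path) {
  sim <- 1 - cosineDistances(set)
  write.table(data.frame(name = rownames(sim), sim, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
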