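# Dunnett many-to-one comparison against control, and sub-sampling power.
#
# The test statistic for dose group i is
#   t_i = (xbar_i - xbar_0) / (s * sqrt(1/n_i + 1/n_0))
# with s^2 the variance pooled over all groups including control. The
# family-wise adjusted p-value is the equicoordinate tail probability of
# the k-variate t distribution with correlation rho_ij =
# sqrt(lambda_i lambda_j), lambda_i = n_i / (n_i + n_0), evaluated by
# mvtnorm's quasi-Monte-Carlo integration under a fixed internal seed so
# p-values are reproducible to about 1e-3.

.withFixedSeed <- function(expr, seed = 20240601L) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.dunnettCorr <- function(n0, ns) {
  lam <- sqrt(ns / (ns + n0))
  R <- outer(lam, lam)
  diag(R) <- 1
  R
}

.stars <- function(p, levels = c(0.05, 0.01, 0.001)) {
  vapply(p, function(x) {
    if (is.na(x)) return("")
    strrep("*", sum(x < levels))
  }, "")
}

#' Dunnett's many-to-one comparison against a shared control
#'
#' Compares each dose group's mean to the control mean with a pooled
#' within-group variance and family-wise adjusted p-values from the
#' equicoordinate multivariate-t distribution. With a single comparison
#' group the adjusted p-value equals the ordinary two-sample pooled t-test
#' p-value.
#'
#' @param control numeric vector of control replicate values (frequencies
#'   per 1e6 class bp in the intended use).
#' @param groups named list of numeric vectors, one per dose group; every
#'   group (and the control) needs at least 2 replicates.
#' @param alternative "two.sided" (default) or "greater" (dose above
#'   control).
#' @param alphaLevels significance levels for the star annotation.
#' @return a [DunnettResult].
#' @examples
#' set.seed(1)
#' dunnettTest(rnorm(3), list(low = rnorm(3), high = rnorm(3, 2)))
#' @export
dunnettTest <- function(control, groups,
                        alternative = c("two.sided", "greater"),
                        alphaLevels = c(0.05, 0.01, 0.001)) {
  alternative <- match.arg(alternative)
  if (!is.list(groups)) groups <- list(group1 = groups)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  all <- c(list(control = control), groups)
  ns <- lengths(all)
  if (any(ns < 2))
    stop("every group needs at least 2 replicates")
  k <- length(groups)
  means <- vapply(all, mean, numeric(1))
  df <- sum(ns) - (k + 1)
  s2 <- sum(vapply(all, function(x) sum((x - mean(x))^2), numeric(1))) / df
  se <- sqrt(s2 * (1 / ns[-1] + 1 / ns[1]))
  diff <- means[-1] - means[1]
  degenerate <- s2 == 0
  if (degenerate) {
    if (all(diff == 0)) {
      warning("zero pooled variance with equal means; no evidence either way")
      p <- rep(1, k)
      stat <- rep(0, k)
    } else {
      warning("zero pooled variance with unequal means; p reported as 0")
      p <- ifelse(diff != 0, 0, 1)
      stat <- ifelse(diff != 0, Inf, 0)
    }
  } else {
    stat <- diff / se
    R <- .dunnettCorr(ns[1], ns[-1])
    p <- vapply(stat, function(t) {
      .withFixedSeed({
        if (alternative == "two.sided") {
          1 - mvtnorm::pmvt(lower = rep(-abs(t), k), upper = rep(abs(t), k),
                            df = df, corr = R, sigma = NULL,
                            algorithm = mvtnorm::GenzBretz(abseps = 1e-4))[1]
        } else {
          1 - mvtnorm::pmvt(lower = rep(-Inf, k), upper = rep(t, k),
                            df = df, corr = R,
                            algorithm = mvtnorm::GenzBretz(abseps = 1e-4))[1]
        }
      })
    }, numeric(1))
    p <- pmin(pmax(p, 0), 1)
  }
  tab <- data.frame(group = names(groups), n = as.integer(ns[-1]),
                    mean = unname(means[-1]), diff = unname(diff),
                    se = if (degenerate) rep(NA_real_, k) else unname(se),
                    statistic = unname(stat), p.adj = unname(p),
                    stars = .stars(p, alphaLevels))
  rownames(tab) <- NULL
  methods::new("DunnettResult", table = tab,
               pooledSD = sqrt(s2), df = as.numeric(df),
               alternative = alternative)
}

setMethod("show", "DunnettResult", function(object) {
  cat("Dunnett many-to-one comparison (", object@alternative,
      "), pooled SD ", signif(object@pooledSD, 4), ", df ", object@df,
      "\n", sep = "")
  print(object@table, digits = 4)
})

#' Table accessor for test and power results
#' @param x a [DunnettResult] or [PowerCurve].
#' @return the underlying data frame.
#' @export
resultTable <- function(x) x@table

#' Equicoordinate Dunnett critical value
#'
#' The critical constant c with
#' P(max_i |T_i| <= c) = 1 - alpha (two-sided) under the null, for the
#' balanced or unbalanced many-to-one design.
#'
#' @param n0 control replicate count.
#' @param ns vector of dose-group replicate counts.
#' @param alpha family-wise level.
#' @param df error degrees of freedom (defaults to the pooled-variance df).
#' @param alternative "two.sided" or "greater".
#' @return the critical value.
#' @export
dunnettCritical <- function(n0, ns, alpha = 0.05, df = NULL,
                            alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (is.null(df)) df <- sum(c(n0, ns)) - (length(ns) + 1)
  R <- .dunnettCorr(n0, ns)
  .withFixedSeed(
    mvtnorm::qmvt(1 - alpha,
                  tail = if (alternative == "two.sided") "both.tails"
                         else "lower.tail",
                  df = df, corr = R,
                  algorithm = mvtnorm::GenzBretz(abseps = 1e-5))$quantile)
}

#' Sub-sampling power analysis
#'
#' Draws without replacement the requested numbers of merged read pairs
#' from every sample, reruns the counting + background-subtraction +
#' Dunnett pipeline at each size, and records which substitution types
#' reach significance. Alignment is deterministic per read, so reads are
#' aligned once per sample and the per-size subsets index into those
#' alignments; duplicate removal, counting and testing are redone per
#' subset.
#'
#' @param samples named list, one entry per sample: a [MergedReads]
#'   object, or a zero-argument function returning one (a generator;
#'   memory-friendly, since each sample is then materialized only while
#'   it is processed).
#' @param groups named character vector mapping sample names to group
#'   labels; the control group must be named "control".
#' @param genome a [ReferenceGenome].
#' @param sizes vector of read counts to draw; each must be at most the
#'   smallest sample size (the full size reproduces the unsubsampled run).
#' @param seed integer seed driving the subsampling draws.
#' @param nIter draws per size (default 1).
#' @param qMin,maxMismatches,dedup pipeline settings.
#' @param alpha significance level for the detection indicator.
#' @param alternative test sidedness, see [dunnettTest()].
#' @param index optional prebuilt [genomeIndex()].
#' @return a [PowerCurve]; its table has one row per (size, iteration,
#'   type) with the mean excess frequency over exposed samples, adjusted
#'   p-value per dose group (minimum across groups) and detection flag
#'   (significant and positive).
#' @export
subsamplePower <- function(samples, groups, genome, sizes, seed = 1,
                           nIter = 1, qMin = 30, maxMismatches = 7,
                           dedup = TRUE, alpha = 0.05,
                           alternative = "two.sided", index = NULL) {
  stopifnot(all(names(samples) %in% names(groups)))
  groups <- groups[names(samples)]
  if (!any(groups == "control")) stop("a control group is required")
  if (is.null(index) && nchar(genome@concat) > 5e4)
    index <- genomeIndex(genome)
  # samples are processed one at a time (materialized if given as a
  # generator, aligned once; subsampling indices refer to merged reads
  # and map onto the alignment rows), so only one sample's reads and
  # alignments are held in memory at once
  mftStore <- list()
  for (i in seq_along(samples)) {
    smp <- samples[[i]]
    if (is.function(smp)) smp <- smp()
    avail <- length(smp)
    if (any(sizes > avail))
      stop("subsample size exceeds available merged pairs (", avail,
           " in sample ", names(samples)[i], ")")
    aligned <- alignExact(smp, genome, maxMismatches = maxMismatches,
                          method = if (is.null(index)) "auto" else
                            "index", index = index)
    alnOf <- match(smp@id, aligned@id)
    rm(smp)
    for (it in seq_len(nIter)) {
      for (s in sizes) {
        set.seed((seed + 104729 * (it - 1) + s %% 104729 +
                    7919 * i) %% .Machine$integer.max)
        take <- sort(sample.int(avail, s))  # keep input order stable
        arow <- alnOf[take]
        a <- aligned[arow[!is.na(arow)]]
        if (dedup) a <- removeDuplicates(a)
        mftStore[[paste(it, s, i)]] <-
          countSubstitutions(buildBaseCounts(a, genome, qMin = qMin),
                             genome, sample = names(samples)[i],
                             group = groups[i])
      }
    }
    rm(aligned)
    gc(FALSE)
  }
  rows <- list()
  delta96BySize <- list()
  for (it in seq_len(nIter)) {
    for (s in sizes) {
      mfts <- lapply(seq_along(samples), function(i)
        mftStore[[paste(it, s, i)]])
      names(mfts) <- names(samples)
      ctrl <- mfts[groups == "control"]
      expo <- mfts[groups != "control"]
      freq <- vapply(mfts, function(x) x@freq6, numeric(6))
      deltas <- vapply(expo, function(x)
        subtractBackground(x, ctrl)@delta6, numeric(6))
      if (it == 1)
        delta96BySize[[as.character(s)]] <-
          rowMeans(vapply(expo, function(x)
            subtractBackground(x, ctrl)@delta96, numeric(96)))
      glabs <- setdiff(unique(groups), "control")
      for (t in SUB_TYPES) {
        dt <- dunnettTest(freq[t, groups == "control"],
                          lapply(setNames(glabs, glabs), function(g)
                            freq[t, groups == g]),
                          alternative = alternative)
        tb <- dt@table
        best <- which.min(tb$p.adj)
        rows[[length(rows) + 1]] <- data.frame(
          size = s, iter = it, type = t,
          meanDelta = mean(deltas[t, ]),
          p.adj = tb$p.adj[best],
          detected = tb$p.adj[best] < alpha & tb$diff[best] > 0)
      }
    }
  }
  out <- methods::new("PowerCurve", table = do.call(rbind, rows),
                      alpha = alpha)
  attr(out@table, "delta96BySize") <- delta96BySize
  out
}

setMethod("show", "PowerCurve", function(object) {
  cat("Subsampling power curve (alpha =", object@alpha, ")\n")
  print(object@table, digits = 4)
})
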