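#' Score a spoken response against a sentence's keywords
#'
#' Case-folds and strips punctuation from both token lists, then credits each
#' keyword at most once if a matching token remains in the response
#' (repeated keywords need repeated response tokens).
#'
#' @param response_tokens character vector of response words.
#' @param keyword_tokens non-empty character vector of scored keywords.
#' @return a list with `n_keywords` and `n_correct`.
#' @examples
#' score_keywords(c("The", "cat", "sat!"), c("cat", "mat", "sat"))
#' @export
score_keywords <- function(response_tokens, keyword_tokens) {
  if (length(keyword_tokens) == 0L) stop("`keyword_tokens` must be non-empty")
  clean <- function(x) {
    x <- tolower(as.character(x))
    x <- gsub("[[:punct:]]", "", x)
    x[nzchar(x)]
  }
  resp <- clean(response_tokens)
  keys <- clean(keyword_tokens)
  n_correct <- 0L
  for (k in keys) {
    hit <- match(k, resp)
    if (!is.na(hit)) {
      n_correct <- n_correct + 1L
      resp <- resp[-hit]
    }
  }
  list(n_keywords = length(keys), n_correct = n_correct)
}

#' Rationalized arcsine unit (RAU) transform
#'
#' Variance-stabilizing transform of proportion-correct scores:
#' `theta = asin(sqrt(X / (N + 1))) + asin(sqrt((X + 1) / (N + 1)))`,
#' `RAU = (146 / pi) * theta - 23`, with `X` keywords correct out of `N`.
#' Defined at both endpoints (X = 0 maps to about -15 RAU for N = 33, X = N
#' to about +115) and near-linear against percent between roughly 20% and
#' 80%.
#'
#' @param n_correct keywords correct (vectorized).
#' @param n_keywords keywords scored (vectorized, >= 1).
#' @return RAU values.
#' @examples
#' rau(0, 33); rau(33, 33); rau(16, 32)
#' @export
rau <- function(n_correct, n_keywords) {
  if (any(n_keywords < 1)) stop("`n_keywords` must be >= 1")
  if (any(n_correct < 0 | n_correct > n_keywords))
    stop("`n_correct` must lie in [0, n_keywords]")
  theta <- asin(sqrt(n_correct / (n_keywords + 1))) +
    asin(sqrt((n_correct + 1) / (n_keywords + 1)))
  (146 / pi) * theta - 23
}

#' Add percent and RAU columns to a long score table
#'
#' @param table data.frame with `n_keywords` and `n_correct` columns.
#' @return the table with `percent` (= 100 * n_correct / n_keywords) and
#'   `rau` columns recomputed.
#' @export
add_score_columns <- function(table) {
  stopifnot(all(c("n_keywords", "n_correct") %in% names(table)))
  table$percent <- 100 * table$n_correct / table$n_keywords
  table$rau <- rau(table$n_correct, table$n_keywords)
  table
}

#' Welch two-sample t-test
#'
#' Unpaired t-test with the Welch-Satterthwaite degrees of freedom, the
#' variant implied by fractional df larger than n - 1 in reported group
#' comparisons.
#'
#' @param group_a,group_b numeric score vectors (each length >= 2).
#' @return a list with `t`, `df` (non-integer), and `p` (two-sided).
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0 &&
      mean(group_a) == mean(group_b))
    stop("t is undefined: both groups constant with equal means")
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

# Orthonormal contrast matrix for a k-level factor (columns orthonormal and
# orthogonal to the constant).
orthonormal_contrasts <- function(k) {
  if (k == 1L) return(matrix(numeric(0), 1, 0))
  qr.Q(qr(cbind(rep(1, k), stats::contr.helmert(k))))[, -1L, drop = FALSE]
}

#' Repeated-measures ANOVA with sphericity handling and generalized
#' eta-squared
#'
#' Univariate within-subject ANOVA for a complete, balanced design with one
#' observation per subject and cell. Every main effect and interaction of
#' the `within` factors is tested by projecting the subject-by-cell matrix
#' onto orthonormal effect contrasts. For effects with more than one
#' numerator df, Mauchly's sphericity test is run and, when its p-value
#' falls below `sphericity_alpha`, the Greenhouse-Geisser epsilon is applied
#' to the degrees of freedom and the reported p-value. Effect sizes are
#' generalized eta-squared (effect SS over effect SS plus all subject and
#' error SS).
#'
#' @param table long-format score table (one row per subject x cell).
#' @param dv dependent-variable column, `"percent"` (default) or `"rau"`.
#' @param within character vector of within-subject factor columns.
#' @param subject subject-identifier column (default `"subject"`).
#' @param sphericity_alpha Mauchly significance level that triggers the
#'   Greenhouse-Geisser correction (default 0.05).
#' @return an `anova_result` data.frame with one row per effect: `effect`,
#'   `F`, `df_num`, `df_den` (corrected when the correction applies), `p`
#'   (likewise), `p_uncorrected`, `ges`, `epsilon`, `sphericity_W`,
#'   `sphericity_p`, `gg_applied`.
#' @export
rm_anova <- function(table, dv = c("percent", "rau"),
                     within = c("silence_added", "spectral_content", "measurement"),
                     subject = "subject", sphericity_alpha = 0.05) {
  dv <- match.arg(dv)
  missing_cols <- setdiff(c(dv, within, subject), names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  facs <- lapply(within, function(f) factor(table[[f]]))
  names(facs) <- within
  levels_list <- lapply(facs, levels)
  k <- vapply(levels_list, length, integer(1))
  subj <- factor(table[[subject]])
  cell <- interaction(rev(facs), lex.order = TRUE)  # expand.grid order
  counts <- table(subj, cell)
  if (any(counts != 1L))
    stop("design must be complete and balanced: exactly one observation per ",
         "subject and within-cell (no imputation is done)")
  cells <- expand.grid(levels_list, stringsAsFactors = FALSE)
  key_data <- do.call(paste, c(lapply(facs, as.character), sep = "\r"))
  key_cells <- do.call(paste, c(cells, sep = "\r"))
  col_idx <- match(key_data, key_cells)
  n <- nlevels(subj)
  p_cells <- nrow(cells)
  Y <- matrix(NA_real_, n, p_cells)
  Y[cbind(as.integer(subj), col_idx)] <- table[[dv]]

  grand <- mean(Y)
  ss_subject <- p_cells * sum((rowMeans(Y) - grand)^2)

  # all non-empty effect subsets, in main-effects-first order
  n_f <- length(within)
  subsets <- unlist(lapply(seq_len(n_f), function(m)
    utils::combn(n_f, m, simplify = FALSE)), recursive = FALSE)

  proj <- lapply(subsets, function(idx) {
    mats <- lapply(seq_len(n_f), function(j) {
      if (j %in% idx) orthonormal_contrasts(k[j])
      else matrix(rep(1 / sqrt(k[j]), k[j]), ncol = 1)
    })
    # expand.grid: factor 1 varies fastest -> it is the rightmost Kronecker term
    U <- Reduce(`%x%`, rev(mats))
    name <- paste(within[idx], collapse = ":")
    list(name = name, U = U)
  })

  res <- lapply(proj, function(pr) {
    Z <- Y %*% pr$U
    d <- ncol(Z)
    zbar <- colMeans(Z)
    ss_eff <- n * sum(zbar^2)
    E <- sweep(Z, 2, zbar)
    ss_err <- sum(E^2)
    df1 <- d
    df2 <- d * (n - 1)
    Fval <- (ss_eff / df1) / (ss_err / df2)
    p_unc <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
    eps <- 1; W <- NA_real_; sph_p <- NA_real_
    if (d >= 2L) {
      S <- crossprod(E) / (n - 1)
      trS <- sum(diag(S))
      eps <- trS^2 / (d * sum(S * S))
      eps <- min(max(eps, 1 / d), 1)
      if (n - 1 > d) {
        detS <- det(S)
        if (detS > 0) {
          W <- detS / (trS / d)^d
          f_corr <- (n - 1) - (2 * d^2 + d + 2) / (6 * d)
          chi <- -f_corr * log(W)
          sph_p <- stats::pchisq(chi, d * (d + 1) / 2 - 1, lower.tail = FALSE)
        }
      }
    }
    apply_gg <- d >= 2L && !is.na(sph_p) && sph_p < sphericity_alpha
    if (apply_gg) {
      df1_r <- eps * df1; df2_r <- eps * df2
      p_r <- stats::pf(Fval, df1_r, df2_r, lower.tail = FALSE)
    } else {
      df1_r <- df1; df2_r <- df2; p_r <- p_unc
    }
    list(effect = pr$name, F = Fval, df_num = df1_r, df_den = df2_r,
         p = p_r, p_uncorrected = p_unc, ss_eff = ss_eff, ss_err = ss_err,
         epsilon = eps, sphericity_W = W, sphericity_p = sph_p,
         gg_applied = apply_gg)
  })

  total_err <- sum(vapply(res, `[[`, numeric(1), "ss_err"))
  out <- do.call(rbind, lapply(res, function(r) {
    data.frame(effect = r$effect, F = r$F, df_num = r$df_num,
               df_den = r$df_den, p = r$p, p_uncorrected = r$p_uncorrected,
               ges = r$ss_eff / (r$ss_eff + ss_subject + total_err),
               epsilon = r$epsilon, sphericity_W = r$sphericity_W,
               sphericity_p = r$sphericity_p, gg_applied = r$gg_applied)
  }))
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Pairwise paired t-tests with Bonferroni correction
#'
#' Post-hoc comparisons between the levels of one factor, computed on
#' per-subject means of the (by default) RAU scores, with p-values
#' multiplied by the number of comparisons and capped at 1.
#'
#' @param table long-format score table.
#' @param contrast factor column to compare.
#' @param dv dependent variable column (default `"rau"`).
#' @param subject subject column.
#' @param correction only `"bonferroni"` is implemented.
#' @return data.frame with `level_a`, `level_b`, `t`, `df`, `p`,
#'   `p_adjusted`.
#' @export
posthoc_pairwise <- function(table, contrast, dv = "rau",
                             subject = "subject",
                             correction = c("bonferroni")) {
  correction <- match.arg(correction)
  if (!contrast %in% names(table)) stop("contrast factor not in table")
  f <- factor(table[[contrast]])
  levs <- levels(f)
  if (length(levs) < 2) stop("contrast factor needs >= 2 levels")
  agg <- stats::aggregate(table[[dv]],
                          by = list(subject = table[[subject]], level = f),
                          FUN = mean)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    a <- agg$x[agg$level == pr[1]][order(agg$subject[agg$level == pr[1]])]
    b <- agg$x[agg$level == pr[2]][order(agg$subject[agg$level == pr[2]])]
    d <- a - b
    if (stats::sd(d) == 0) {
      tval <- 0; df <- length(d) - 1; p <- 1
    } else {
      ht <- stats::t.test(a, b, paired = TRUE)
      tval <- unname(ht$statistic); df <- unname(ht$parameter)
      p <- unname(ht$p.value)
    }
    data.frame(level_a = pr[1], level_b = pr[2], t = tval, df = df, p = p,
               p_adjusted = min(1, p * m))
  })
  do.call(rbind, rows)
}

#' Repackaging benefit per subject and spectral content
#'
#' The benefit of restoring the syllabic rhythm: score with silences added
#' minus score without, computed per subject and spectral-content condition
#' after averaging the test and retest measurements, in both percentage
#' points and RAU.
#'
#' @param table long-format score table containing silence and no-silence
#'   rows for every spectral content.
#' @return data.frame with `subject`, `spectral_content`, `benefit_percent`,
#'   `benefit_rau`.
#' @export
repackaging_benefit <- function(table) {
  needed <- c("subject", "spectral_content", "silence_added", "percent", "rau")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  agg <- stats::aggregate(cbind(percent, rau) ~ subject + spectral_content +
                            silence_added, data = table, FUN = mean)
  yes <- agg[agg$silence_added == TRUE, ]
  no <- agg[agg$silence_added == FALSE, ]
  key <- function(d) paste(d$subject, d$spectral_content, sep = "\r")
  idx <- match(key(yes), key(no))
  if (any(is.na(idx)) || nrow(yes) != nrow(no))
    stop("table must contain both silence and no-silence rows for every ",
         "subject and spectral content")
  out <- data.frame(subject = yes$subject,
                    spectral_content = yes$spectral_content,
                    benefit_percent = yes$percent - no$percent[idx],
                    benefit_rau = yes$rau - no$rau[idx])
  out[order(out$spectral_content, out$subject), ]
}

#' Shapiro-Wilk normality check
#'
#' @param values numeric vector (>= 3 non-constant values).
#' @return list with `W` and `p`.
#' @export
normality_check <- function(values) {
  if (length(values) < 3) stop("need at least 3 values")
  if (stats::sd(values) == 0) stop("constant input: normality test undefined")
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = unname(ht$p.value))
}
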