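## Factorial statistics over depth x temperature x enzyme: ANOVA (fixed
## two-way, and blocked with temperature as block), Tukey HSD with compact
## letter displays, assumption diagnostics, percent-decline summaries, and
## between-enzyme trait ratios.

#' Two-way fixed-effects ANOVA
#'
#' Type-I (sequential) sums of squares via `aov`, optionally with the
#' interaction and an ln-transformed response.
#'
#' @param data data.frame.
#' @param response name of the response column.
#' @param factor_a,factor_b names of the two factor columns (coerced to
#'   factor).
#' @param interaction include the A:B interaction.
#' @param ln_transform ln-transform the response first.
#' @return list with `table` (term, df, sum_sq, F, p; p for a constant
#'   response reported as 1) and the underlying `aov` fit.
#' @export
anova_two_way <- function(data, response, factor_a = "depth_cm",
                          factor_b = "temperature_C", interaction = TRUE,
                          ln_transform = FALSE) {
  d <- data.frame(y = data[[response]],
                  A = factor(data[[factor_a]]),
                  B = factor(data[[factor_b]]))
  d <- d[is.finite(d$y), ]
  if (nlevels(droplevels(d$A)) < 2 || nlevels(droplevels(d$B)) < 2)
    stop("both factors need >= 2 observed levels")
  if (interaction && any(table(d$A, d$B) == 0))
    stop("design error: empty cells with interaction requested")
  if (ln_transform) {
    if (any(d$y <= 0)) stop("ln transform requires a positive response")
    d$y <- log(d$y)
  }
  form <- if (interaction) y ~ A * B else y ~ A + B
  fit <- aov(form, data = d)
  s <- summary(fit)[[1]]
  tab <- data.frame(term = trimws(rownames(s)), df = s$Df,
                    sum_sq = s$`Sum Sq`, F = s$`F value`,
                    p = s$`Pr(>F)`, row.names = NULL)
  tab$term[tab$term == "A"] <- factor_a
  tab$term[tab$term == "B"] <- factor_b
  tab$term[tab$term == "A:B"] <- paste0(factor_a, ":", factor_b)
  ## degenerate (constant) response: all SS at rounding noise; report p = 1
  not_res <- tab$term != "Residuals"
  degenerate <- sum(tab$sum_sq) <= 1e-18 * max(1, mean(d$y)^2) * nrow(d)
  fix <- not_res & (degenerate | is.nan(tab$F) | is.na(tab$p))
  tab$p[fix] <- 1
  tab$F[not_res & (degenerate | is.nan(tab$F))] <- 0
  list(table = tab, fit = fit, design = if (interaction) "two_way_fixed"
       else "two_way_additive", ln_transform = ln_transform)
}

#' Blocked ANOVA (randomised complete block)
#'
#' Tests the factor of interest against the residual after removing block
#' variation (sequential SS, block entered first); no interaction term.
#' With a single block this reduces to a one-way ANOVA.
#'
#' @param data data.frame.
#' @param response response column name.
#' @param factor factor of interest (e.g. depth).
#' @param block block variable (e.g. temperature).
#' @return as [anova_two_way()].
#' @export
anova_blocked <- function(data, response, factor = "depth_cm",
                          block = "temperature_C") {
  d <- data.frame(y = data[[response]],
                  f = factor(data[[factor]]),
                  b = factor(data[[block]]))
  d <- d[is.finite(d$y), ]
  cells <- table(d$f, d$b)
  if (any(cells == 0)) {
    miss <- which(cells == 0, arr.ind = TRUE)
    stop("unbalanced blocks: missing cell(s) ",
         paste(rownames(cells)[miss[, 1]], colnames(cells)[miss[, 2]],
               sep = "@", collapse = ", "))
  }
  single_block <- nlevels(droplevels(d$b)) < 2
  fit <- if (single_block) aov(y ~ f, data = d) else aov(y ~ b + f, data = d)
  s <- summary(fit)[[1]]
  tab <- data.frame(term = trimws(rownames(s)), df = s$Df,
                    sum_sq = s$`Sum Sq`, F = s$`F value`,
                    p = s$`Pr(>F)`, row.names = NULL)
  tab$term[tab$term == "f"] <- factor
  tab$term[tab$term == "b"] <- block
  list(table = tab, fit = fit, design = "blocked", ln_transform = FALSE)
}

#' Tukey HSD with a compact letter display
#'
#' Studentised-range adjusted pairwise p-values via `TukeyHSD`, lettered
#' with an insert-and-absorb algorithm: groups sorted by descending mean
#' receive letters such that two levels share a letter iff their adjusted
#' p exceeds `alpha`.
#'
#' @param anova result of [anova_two_way()] / [anova_blocked()], or an
#'   `aov` fit.
#' @param factor name of the model term to compare (as used in the `aov`
#'   formula, e.g. `"A"` for [anova_two_way()] fits or `"f"` for
#'   [anova_blocked()]; defaults to the first term).
#' @param alpha significance level.
#' @return list with `p_matrix` (adjusted pairwise p), `letters`
#'   (data.frame `level, mean, letters`, sorted by descending mean).
#' @export
tukey_cld <- function(anova, factor = NULL, alpha = 0.05) {
  fit <- if (inherits(anova, "aov")) anova else anova$fit
  hsd <- TukeyHSD(fit)
  if (is.null(factor)) factor <- names(hsd)[1]
  tab <- hsd[[factor]]
  pairs <- strsplit(rownames(tab), "-", fixed = TRUE)
  levels_all <- unique(unlist(pairs))
  p <- matrix(1, length(levels_all), length(levels_all),
              dimnames = list(levels_all, levels_all))
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    p[a, b] <- p[b, a] <- tab[i, "p adj"]
  }
  mf <- fit$model
  fac_col <- mf[[factor]]
  means <- tapply(mf[[1]], fac_col, mean)[levels_all]
  ord <- order(-means)
  lv <- levels_all[ord]
  letters_df <- data.frame(level = lv, mean = as.numeric(means[ord]),
                           letters = cld_letters(p[lv, lv, drop = FALSE],
                                                 alpha),
                           row.names = NULL)
  list(p_matrix = p, letters = letters_df, alpha = alpha)
}

#' Insert-and-absorb compact letter display
#'
#' @param p symmetric matrix of adjusted pairwise p-values whose row order
#'   determines letter precedence (typically descending group mean).
#' @param alpha significance level.
#' @return character vector of letter strings, one per row of `p`.
#' @export
cld_letters <- function(p, alpha = 0.05) {
  g <- nrow(p)
  if (g == 1) return("a")
  cols <- list(rep(TRUE, g))   # letter columns: membership masks
  for (i in seq_len(g - 1)) for (j in seq((i + 1), g)) {
    if (p[i, j] <= alpha) {
      for (ci in seq_along(cols)) {
        m <- cols[[ci]]
        if (m[i] && m[j]) {           # split the offending column
          m1 <- m; m1[j] <- FALSE
          m2 <- m; m2[i] <- FALSE
          cols[[ci]] <- m1
          cols[[length(cols) + 1]] <- m2
        }
      }
      ## absorb columns that are subsets of another
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) for (b in seq_along(cols)) {
        if (a != b && keep[a] && keep[b] &&
            all(cols[[a]] <= cols[[b]]) && any(cols[[b]] & !cols[[a]]))
          keep[a] <- FALSE
        else if (a < b && keep[a] && keep[b] &&
                 all(cols[[a]] == cols[[b]]))
          keep[b] <- FALSE
      }
      cols <- cols[keep]
    }
  }
  ## order columns by first member so surface groups letter first
  first <- vapply(cols, function(m) which(m)[1], numeric(1))
  cols <- cols[order(first)]
  vapply(seq_len(g), function(i) {
    paste(letters[which(vapply(cols, function(m) m[i], logical(1)))],
          collapse = "")
  }, character(1))
}

#' ANOVA assumption diagnostics
#'
#' Levene's test (median-centred), Shapiro-Wilk on residuals, and residual
#' skewness. Advisory only: the pipeline proceeds and logs warnings.
#'
#' @param residuals model residuals.
#' @param groups grouping factor for Levene (e.g. the cell of the design).
#' @return list with `levene` (statistic, p), `shapiro` (statistic, p),
#'   `skewness`; `NULL` entries when `n < 3`.
#' @export
assumption_checks <- function(residuals, groups) {
  if (length(residuals) < 3) {
    message("fewer than 3 residuals: assumption checks skipped")
    return(list(levene = NULL, shapiro = NULL, skewness = NULL))
  }
  groups <- factor(groups)
  lev <- tryCatch({
    lt <- car::leveneTest(residuals ~ groups, center = median)
    list(statistic = lt[1, "F value"], p = lt[1, "Pr(>F)"])
  }, error = function(e) NULL)
  shp <- tryCatch({
    st <- shapiro.test(residuals)
    list(statistic = unname(st$statistic), p = st$p.value)
  }, error = function(e) NULL)
  list(levene = lev, shapiro = shp,
       skewness = e1071::skewness(residuals))
}

#' Percent decline of a trait down the profile
#'
#' Per temperature: `100 * (max(upper) - min(lower)) / max(upper)` where
#' `upper`/`lower` are the trait values (depth means) within the upper and
#' lower depth ranges; then mean and standard error across temperatures.
#'
#' @param data data.frame with `depth_cm`, `temperature_C` and the trait.
#' @param response trait column name.
#' @param upper_depths,lower_depths depth labels defining the two ranges.
#' @param exclude_cells optional data.frame `depth_cm, temperature_C` of
#'   cells excluded as spurious before the computation.
#' @return list: `per_temperature` (data.frame), `mean`, `se`.
#' @export
percent_decline <- function(data, response,
                            upper_depths = c("0-10", "10-20"),
                            lower_depths = c("60-70", "80-90"),
                            exclude_cells = NULL) {
  if (!is.null(exclude_cells) && nrow(exclude_cells) > 0) {
    drop <- paste(data$depth_cm, data$temperature_C) %in%
      paste(exclude_cells$depth_cm, exclude_cells$temperature_C)
    data <- data[!drop, ]
  }
  agg <- aggregate(data[[response]],
                   list(depth_cm = data$depth_cm,
                        temperature_C = data$temperature_C), mean,
                   na.rm = TRUE)
  names(agg)[3] <- "value"
  per_t <- vapply(split(agg, agg$temperature_C), function(d) {
    up <- d$value[d$depth_cm %in% upper_depths]
    lo <- d$value[d$depth_cm %in% lower_depths]
    if (length(up) == 0 || length(lo) == 0) return(NA_real_)
    if (max(up) <= 0) return(NA_real_)
    100 * (max(up) - min(lo)) / max(up)
  }, numeric(1))
  per_t <- per_t[is.finite(per_t)]
  data.frame(temperature_C = as.numeric(names(per_t)),
             percent_decline = as.numeric(per_t)) -> tab
  list(per_temperature = tab,
       mean = mean(per_t),
       se = sd(per_t) / sqrt(length(per_t)))
}

#' Ratios of kinetic traits between enzymes
#'
#' Element-wise Vmax, Km and CE ratios for the enzyme pairs BG:LAP, BG:AP
#' and LAP:AP at common depth x temperature x core coordinates.
#'
#' @param traits trait table from [derive_traits_all()].
#' @return data.frame with one row per coordinate x pair and columns
#'   `vmax_ratio, km_ratio, ce_ratio` (`NA` where a partner is missing or
#'   its denominator zero).
#' @export
enzyme_ratios <- function(traits) {
  pairs <- list(c("BG", "LAP"), c("BG", "AP"), c("LAP", "AP"))
  coord <- c("depth_cm", "core", "temperature_C")
  out <- lapply(pairs, function(pr) {
    a <- traits[traits$enzyme == pr[1], c(coord, "vmax_ds", "km", "ce_ds")]
    b <- traits[traits$enzyme == pr[2], c(coord, "vmax_ds", "km", "ce_ds")]
    m <- merge(a, b, by = coord, suffixes = c("_a", "_b"))
    if (nrow(m) == 0) return(NULL)
    safe_div <- function(x, y) ifelse(is.finite(y) & y != 0, x / y, NA_real_)
    data.frame(pair = paste(pr, collapse = ":"), m[coord],
               vmax_ratio = safe_div(m$vmax_ds_a, m$vmax_ds_b),
               km_ratio = safe_div(m$km_a, m$km_b),
               ce_ratio = safe_div(m$ce_ds_a, m$ce_ds_b))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
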