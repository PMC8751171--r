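#' Distance-decay buffer selection
#'
#' For one predictor family measured at several buffer radii, picks the radius
#' whose column has the highest absolute Pearson correlation with the
#' response, and returns the full correlation-vs-radius curve. Ties go to the
#' smallest radius. A family that is constant at every radius is dropped
#' (returned radius NA) with a message.
#'
#' @param response numeric response vector.
#' @param table data.frame holding the family columns.
#' @param family_cols named character vector: names are radii (m), values are
#'   column names, e.g. `c("50" = "RES_50", ...)`.
#' @return list with `radius` (chosen, numeric or NA), `col` (chosen column),
#'   and `curve` (data.frame radius, r).
#' @export
distance_decay_select <- function(response, table, family_cols) {
  radii <- as.numeric(names(family_cols))
  r <- vapply(family_cols, function(cn) {
    x <- table[[cn]]
    if (stats::sd(x) < 1e-12 || stats::sd(response) < 1e-12) return(NA_real_)
    stats::cor(response, x)
  }, 0)
  curve <- data.frame(radius = radii, r = unname(r))
  if (all(is.na(r))) {
    message("family ", sub("_[0-9]+$", "", family_cols[1]),
            " constant at all radii: dropped")
    return(list(radius = NA_real_, col = NA_character_, curve = curve))
  }
  best <- which(abs(r) == max(abs(r), na.rm = TRUE))  # tie -> smallest radius
  best <- best[which.min(radii[best])]
  list(radius = radii[best], col = unname(family_cols[best]), curve = curve)
}

# variance inflation factors of the terms of a fitted lm (intercept excluded)
model_vif <- function(fit) {
  X <- stats::model.matrix(fit)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) < 2) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  v <- vapply(seq_len(ncol(X)), function(j) {
    res <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])$residuals
    rsq <- 1 - sum(res^2) / sum((X[, j] - mean(X[, j]))^2)
    1 / max(1 - rsq, 1e-12)
  }, 0)
  stats::setNames(v, colnames(X))
}

term_pvalues <- function(fit) {
  cf <- summary(fit)$coefficients
  p <- cf[, 4]
  p[names(p) != "(Intercept)"]
}

#' Bidirectional stepwise screening with the LUR acceptance rules
#'
#' Starting from the forced set (the AOD column at city scale), candidates are
#' tried in decreasing order of the |t| statistic they would have if added; a
#' variable enters only if its p-value is below `alpha` after entry and every
#' VIF (intercept excluded) stays below `vif_max`. After each entry, non-forced
#' variables whose p-value has risen to `alpha` or above are removed (worst
#' first). The procedure is deterministic and invariant to row and column
#' order. Constant candidates are dropped up front.
#'
#' @param table data.frame of candidate predictor columns.
#' @param response numeric response vector (same row order as `table`).
#' @param candidates character vector of candidate column names.
#' @param forced character vector of columns always kept (default `"AOD"`).
#' @param alpha significance threshold (default 0.05).
#' @param vif_max VIF bound (default 3).
#' @return list with `selected` (non-forced survivors), `forced`, `fit` (the
#'   final `lm`), `p` and `vif` of the final terms, and a `trace` data.frame
#'   of entry/removal events.
#' @export
stepwise_select <- function(table, response, candidates,
                            forced = "AOD", alpha = 0.05, vif_max = 3) {
  if (!all(forced %in% names(table)))
    stop("forced variable(s) missing from the table: ",
         paste(setdiff(forced, names(table)), collapse = ", "))
  keep <- vapply(candidates, function(cn) stats::sd(table[[cn]]) > 1e-12,
                 TRUE)
  candidates <- setdiff(candidates[keep], forced)
  dat <- cbind(.y = response, table[, c(forced, candidates), drop = FALSE])
  current <- character(0)
  trace <- list()
  refit <- function(vars) {
    fml <- stats::reformulate(c(forced, vars) %||chr% "1", response = ".y")
    stats::lm(fml, data = dat)
  }
  repeat {
    changed <- FALSE
    pool <- setdiff(candidates, current)
    if (length(pool)) {
      tvals <- vapply(pool, function(cn) {
        f <- refit(c(current, cn))
        cf <- summary(f)$coefficients
        if (!cn %in% rownames(cf)) return(0)
        tv <- abs(cf[cn, 3])
        if (is.finite(tv)) tv else 0
      }, 0)
      for (cn in pool[order(-tvals)]) {
        f <- refit(c(current, cn))
        cf <- summary(f)$coefficients
        if (!cn %in% rownames(cf)) next          # aliased
        pv <- cf[cn, 4]
        vif <- model_vif(f)
        if (is.finite(pv) && pv < alpha && all(vif < vif_max)) {
          current <- c(current, cn); changed <- TRUE
          trace[[length(trace) + 1]] <- data.frame(step = "enter", var = cn,
                                                   p = pv, max_vif = max(vif))
          break
        } else break  # p is monotone in |t| at fixed df: only the best can pass
      }
    }
    # backward pass: drop non-forced terms that lost significance
    repeat {
      f <- refit(current)
      pv <- term_pvalues(f)
      pv <- pv[names(pv) %in% current]
      pv[!is.finite(pv)] <- 1
      bad <- pv[pv >= alpha]
      if (!length(bad)) break
      worst <- names(bad)[which.max(bad)]
      current <- setdiff(current, worst); changed <- TRUE
      trace[[length(trace) + 1]] <- data.frame(step = "remove", var = worst,
                                               p = max(bad), max_vif = NA)
    }
    if (!changed) break
  }
  fit <- refit(current)
  list(selected = current, forced = forced, fit = fit,
       p = term_pvalues(fit), vif = model_vif(fit),
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = character(), var = character(),
                    p = numeric(), max_vif = numeric()))
}

`%||chr%` <- function(a, b) if (length(a)) a else b

#' Reduce every buffer family to its distance-decay radius
#'
#' Applies [distance_decay_select()] to each spatial family in a predictor
#' table (using its schema attribute) and returns the chosen columns together
#' with the temporal/location columns, ready for [stepwise_select()].
#'
#' @param table a `predictor_table` from [assemble_table()].
#' @param response numeric response (defaults to `table$pm25`).
#' @return list with `chosen` (data.frame family, radius, col), `curves`,
#'   and `candidates` (character vector of screened columns).
#' @export
select_buffer_radii <- function(table, response = table$pm25) {
  schema <- attr(table, "schema")
  fams <- unique(schema$var[!is.na(schema$radius)])
  chosen <- list(); curves <- list()
  for (fm in fams) {
    sub <- schema[schema$var == fm & !is.na(schema$radius), ]
    fc <- stats::setNames(sub$col, sub$radius)
    dd <- distance_decay_select(response, table, fc)
    curves[[fm]] <- dd$curve
    chosen[[fm]] <- data.frame(family = fm, radius = dd$radius, col = dd$col)
  }
  chosen <- do.call(rbind, chosen)
  scalar <- schema$col[is.na(schema$radius)]
  cand <- c(chosen$col[!is.na(chosen$radius)], scalar)
  list(chosen = chosen, curves = curves,
       candidates = setdiff(cand, "AOD"))
}
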