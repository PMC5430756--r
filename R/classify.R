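#' Read and validate a brood table
#'
#' Brood tables are TSV with header
#' `species  brood_id  n_male  n_female  mother_wolbachia`, one row per F1
#' progeny; `mother_wolbachia` is one of `positive`, `negative`,
#' `untested`.
#'
#' @param path path to a TSV file.
#' @return data frame of broods.
#' @export
read_broods <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_broods(df)
}

validate_broods <- function(df) {
  need <- c("species", "brood_id", "n_male", "n_female", "mother_wolbachia")
  if (!all(need %in% names(df)))
    stop("brood table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("no-data: empty brood table", call. = FALSE)
  with(df, invisible(mapply(check_counts, n_male, n_female)))
  bad <- !df$mother_wolbachia %in% c("positive", "negative", "untested")
  if (any(bad))
    stop("mother_wolbachia must be positive/negative/untested", call. = FALSE)
  df
}

#' Filter broods before classification
#'
#' Applies the study's two discard rules in fixed order: (1) broods whose
#' mother tested Wolbachia-positive are removed (feminizing Wolbachia
#' biases the brood toward females and mimics the heterogamety signal);
#' (2) broods whose sex ratio does not differ significantly from 1:1 at
#' level `alpha` are removed, the interpretation being that the implanted
#' individual was an undifferentiated genetic male rather than a female,
#' so the cross was an ordinary male x female one. A Wolbachia-positive
#' brood that is also balanced is discarded with reason `wolbachia`
#' (rule precedence).
#'
#' @param broods a brood data frame (see [read_broods()]).
#' @param alpha significance level for the balanced-ratio test.
#' @param untested how to treat `mother_wolbachia == "untested"`:
#'   `"negative"` (default, keep through step 1) or `"discard"`. Either
#'   way a warning reports how many broods were untested.
#' @return list of class `"sd_filter"` with `kept` (data frame) and
#'   `discarded` (data frame with an extra `reason` column,
#'   `wolbachia` or `balanced_sex_ratio`).
#' @export
filter_broods <- function(broods, alpha = 0.05,
                          untested = c("negative", "discard")) {
  broods <- validate_broods(broods)
  untested <- match.arg(untested)
  n_unt <- sum(broods$mother_wolbachia == "untested")
  if (n_unt > 0)
    warning(n_unt, " brood(s) with untested Wolbachia status treated as ",
            untested, call. = FALSE)
  drop_wol <- broods$mother_wolbachia == "positive" |
    (untested == "discard" & broods$mother_wolbachia == "untested")
  p_bal <- mapply(function(m, f) chisq_gof(m, f, 0.5)$p.value,
                  broods$n_male, broods$n_female)
  drop_bal <- !drop_wol & p_bal >= alpha
  reason <- ifelse(drop_wol, "wolbachia",
                   ifelse(drop_bal, "balanced_sex_ratio", NA))
  discarded <- broods[!is.na(reason), , drop = FALSE]
  discarded$reason <- reason[!is.na(reason)]
  structure(list(kept = broods[is.na(reason), , drop = FALSE],
                 discarded = discarded),
            class = "sd_filter")
}

#' @export
print.sd_filter <- function(x, ...) {
  cat("Brood filter:", nrow(x$kept), "kept,",
      sum(x$discarded$reason == "wolbachia"), "discarded (Wolbachia),",
      sum(x$discarded$reason == "balanced_sex_ratio"),
      "discarded (balanced sex ratio)\n")
  invisible(x)
}

#' Classify a species' heterogametic system from filtered broods
#'
#' Implements the decision procedure used on the crossing data. Broods are
#' first checked for heterogeneity of sex ratios ([heterogeneity_test()]);
#' if significantly heterogeneous the species is left `UNDETERMINED`
#' (flag `heterogeneous`) and no pooling is done. Otherwise counts are
#' pooled and tested against three expectations:
#' balanced 1:1, the ZW predictions 1/3 male (WW inviable) and 1/4 male
#' (WW viable), and the XY prediction of zero males
#' ([exact_zero_male_test()]). The verdict is
#' \itemize{
#'   \item `UNDETERMINED` (flag `male_excess`) when males are at least
#'     half the pooled progeny and significantly exceed 1:1 -- the
#'     all-male Armadillidium assimile pattern, which no heterogametic
#'     prediction explains;
#'   \item `XY` when the zero-male test is not rejected while both ZW
#'     expectations are;
#'   \item otherwise `ZW`, with WW viability `viable` when only the 1/3
#'     expectation is rejected, `inviable` when only the 1/4 expectation
#'     is, `indeterminate` when neither is (e.g. the 30 Porcellio scaber
#'     offspring), and system `UNDETERMINED` when all expectations
#'     including XY are rejected.
#' }
#'
#' @param broods filtered broods of a single species.
#' @param alpha significance level.
#' @param male_leak_rate leak rate for the XY exact test.
#' @return list of class `"sd_call"`: species, pooled counts, p-values
#'   (`p_balanced`, `p_onethird`, `p_onequarter`, `p_zero_male`,
#'   `heterogeneity_p`), `system`, `ww_viability`, `flags`, `n_broods`.
#' @export
classify_species <- function(broods, alpha = 0.05, male_leak_rate = 0) {
  broods <- validate_broods(broods)
  sp <- unique(broods$species)
  if (length(sp) != 1L)
    stop("classify_species expects broods of a single species", call. = FALSE)
  flags <- character(0)

  m <- broods$n_male
  f <- broods$n_female
  het_p <- NA_real_
  if (nrow(broods) >= 2L) {
    if (sum(m) == 0 || sum(f) == 0) {
      # one sex absent in every brood: proportions are identical by
      # construction, the contingency table is degenerate but trivially
      # homogeneous -- pooling is allowed
      flags <- c(flags, "degenerate_heterogeneity_table")
    } else {
      het_p <- heterogeneity_test(broods)$p.value
      if (het_p < alpha)
        return(new_call(sp, sum(m), sum(f), rep(NA_real_, 4), het_p,
                        "UNDETERMINED", "not_applicable",
                        c(flags, "heterogeneous"), nrow(broods)))
    }
  }

  pm <- sum(m); pf <- sum(f); n <- pm + pf
  p_bal <- chisq_gof(pm, pf, 0.5)$p.value
  p_13  <- chisq_gof(pm, pf, 1 / 3)$p.value
  p_14  <- chisq_gof(pm, pf, 1 / 4)$p.value
  p_xy  <- exact_zero_male_test(pm, pf, male_leak_rate)
  ps <- c(p_bal, p_13, p_14, p_xy)

  if (pm / n >= 0.5 && p_bal < alpha) {
    # significant male excess: outside both heterogametic predictions
    return(new_call(sp, pm, pf, ps, het_p, "UNDETERMINED", "not_applicable",
                    c(flags, "male_excess"), nrow(broods)))
  }
  if (p_xy >= alpha && p_13 < alpha && p_14 < alpha) {
    if (n < 20) flags <- c(flags, "low_power")
    return(new_call(sp, pm, pf, ps, het_p, "XY", "not_applicable",
                    flags, nrow(broods)))
  }
  if (pm == 0 && p_xy >= alpha) {
    # all-female but too few offspring to reject both ZW expectations:
    # an XY candidate, flagged rather than forced into a ZW verdict
    return(new_call(sp, pm, pf, ps, het_p, "XY", "not_applicable",
                    c(flags, "xy_candidate", "low_power"), nrow(broods)))
  }
  viab <-
    if (p_13 < alpha && p_14 >= alpha) "viable"
    else if (p_14 < alpha && p_13 >= alpha) "inviable"
    else if (p_13 >= alpha && p_14 >= alpha) "indeterminate"
    else NA  # both ZW nulls rejected (and XY rejected too)
  if (is.na(viab))
    return(new_call(sp, pm, pf, ps, het_p, "UNDETERMINED", "not_applicable",
                    c(flags, "all_nulls_rejected"), nrow(broods)))
  new_call(sp, pm, pf, ps, het_p, "ZW", viab, flags, nrow(broods))
}

new_call <- function(species, pooled_m, pooled_f, ps, het_p, system,
                     ww_viability, flags, n_broods) {
  structure(list(species = species, pooled_m = pooled_m, pooled_f = pooled_f,
                 p_balanced = ps[1], p_onethird = ps[2], p_onequarter = ps[3],
                 p_zero_male = ps[4], heterogeneity_p = het_p,
                 system = system, ww_viability = ww_viability,
                 flags = flags, n_broods = n_broods),
            class = "sd_call")
}

#' @export
print.sd_call <- function(x, ...) {
  cat(sprintf("%s: %s (WW %s), pooled %dM:%dF over %d brood(s)\n",
              x$species, x$system, x$ww_viability,
              x$pooled_m, x$pooled_f, x$n_broods))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Filter and classify every species in a brood table
#'
#' Convenience wrapper: [filter_broods()] on the whole table, then
#' [classify_species()] per species with at least one kept brood.
#'
#' @inheritParams filter_broods
#' @inheritParams classify_species
#' @return list with `filter` (the [filter_broods()] report), `calls`
#'   (list of `sd_call`), and `summary` (one data frame row per species).
#' @export
call_heterogamety <- function(broods, alpha = 0.05, male_leak_rate = 0,
                              untested = "negative") {
  fr <- filter_broods(broods, alpha = alpha, untested = untested)
  calls <- lapply(split(fr$kept, fr$kept$species), classify_species,
                  alpha = alpha, male_leak_rate = male_leak_rate)
  summary <- do.call(rbind, lapply(calls, function(cl)
    data.frame(species = cl$species, system = cl$system,
               ww_viability = cl$ww_viability,
               pooled_m = cl$pooled_m, pooled_f = cl$pooled_f,
               n_broods = cl$n_broods,
               p_balanced = cl$p_balanced, p_onethird = cl$p_onethird,
               p_onequarter = cl$p_onequarter, p_zero_male = cl$p_zero_male,
               flags = paste(cl$flags, collapse = ";"))))
  rownames(summary) <- NULL
  list(filter = fr, calls = calls, summary = summary)
}
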