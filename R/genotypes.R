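#' Sex chromosome genotypes
#'
#' A genotype is an unordered pair of sex chromosome alleles. Only the six
#' pairs that arise in single-locus heterogametic systems are constructible:
#' XX, XY (male heterogamety) and ZZ, ZW, WW, YY (female heterogamety plus
#' the two sex-limited-chromosome homozygotes producible in neomale
#' crosses). Sex phenotype is derivable from the genotype -- XX and ZW (and
#' WW, when viable) are female; XY, ZZ and YY are male -- unless overridden
#' by a sex-reversal flag (a neomale is a genetic female implanted with
#' androgenic glands and functioning as a phenotypic male) or by Wolbachia
#' feminization (a genetic male carrying the feminizing endosymbiont and
#' functioning as a female).
#'
#' @param alleles character vector of two alleles among "X","Y","Z","W",
#'   or a two-letter string such as "ZW".
#' @param reversed logical; `TRUE` marks a sex-reversed individual whose
#'   functional phenotype is the opposite of its genotypic sex (neomale
#'   when genotypically female, feminized male when genotypically male).
#' @return An object of class `"sd_genotype"`: a list with elements
#'   `alleles` (sorted pair), `reversed`, and `label` (e.g. `"ZW"`).
#' @examples
#' genotype("ZW")                    # a genetic female
#' genotype("ZW", reversed = TRUE)   # a neomale
#' @export
genotype <- function(alleles, reversed = FALSE) {
  if (is.character(alleles) && length(alleles) == 1L && nchar(alleles) == 2L)
    alleles <- strsplit(alleles, "")[[1]]
  if (length(alleles) != 2L || !all(alleles %in% c("X", "Y", "Z", "W")))
    stop("alleles must be a pair over {X, Y, Z, W}", call. = FALSE)
  alleles <- sort(alleles)
  label <- paste(alleles, collapse = "")
  valid <- c("XX", "XY", "YY", "ZZ", "WZ", "WW")
  if (!label %in% valid)
    stop("non-constructible genotype: ", label,
         " (X/Y and Z/W systems do not mix)", call. = FALSE)
  # display W second for ZW, matching field usage
  disp <- if (label == "WZ") "ZW" else label
  structure(list(alleles = alleles, reversed = isTRUE(reversed), label = disp),
            class = "sd_genotype")
}

#' @export
print.sd_genotype <- function(x, ...) {
  cat(x$label,
      if (x$reversed) "(sex-reversed)" else "",
      "-", genotypic_sex(x), "genotypic sex,",
      phenotypic_sex(x), "functional phenotype\n")
  invisible(x)
}

#' Genotypic sex implied by a genotype
#'
#' XX, ZW and WW are genotypically female; XY, ZZ and YY genotypically male.
#'
#' @param g an [genotype()] object.
#' @return `"female"` or `"male"`.
#' @export
genotypic_sex <- function(g) {
  stopifnot(inherits(g, "sd_genotype"))
  if (g$label %in% c("XX", "ZW", "WW")) "female" else "male"
}

#' Functional (phenotypic) sex of an individual
#'
#' The genotypic sex, flipped when the individual carries the reversal /
#' feminization flag.
#'
#' @inheritParams genotypic_sex
#' @return `"female"` or `"male"`.
#' @export
phenotypic_sex <- function(g) {
  s <- genotypic_sex(g)
  if (g$reversed) c(female = "male", male = "female")[[s]] else s
}

#' Viability configuration for sex-limited-chromosome homozygotes
#'
#' WW and YY genotypes arise only when two carriers of the sex-limited
#' chromosome are crossed. Their viability is diagnostic: a viable WW
#' implies largely homomorphic Z and W. YY viability has been confirmed
#' experimentally in most XY isopods and defaults to viable; it does not
#' affect neomale x sister crosses under female heterogamety.
#'
#' @param ww_viable,yy_viable logicals.
#' @return A list of class `"sd_viability"`.
#' @export
viability_config <- function(ww_viable = TRUE, yy_viable = TRUE) {
  stopifnot(is.logical(ww_viable), is.logical(yy_viable),
            length(ww_viable) == 1L, length(yy_viable) == 1L)
  structure(list(ww_viable = ww_viable, yy_viable = yy_viable),
            class = "sd_viability")
}

#' Mendelian prediction for a cross between two sex chromosome genotypes
#'
#' Forms the 2x2 gamete union with equal gamete probabilities, removes
#' inviable genotypes per `viability` and renormalizes, and assigns sex by
#' genotype. The cross validates on functional phenotype: the two parents
#' must be of opposite functional sex, so a neomale (genotypically female,
#' `reversed = TRUE`) can sire a brood on its sister. This is the principle
#' of the sex-reversal crossing design: under female heterogamety a ZW
#' neomale x ZW female cross yields 25% ZZ males and 75% ZW+WW females if
#' WW is viable (1/3 males if not), while under male heterogamety an XX
#' neomale x XX female cross yields 100% XX females.
#'
#' @param parent1,parent2 [genotype()] objects of opposite functional sex.
#' @param viability an [viability_config()].
#' @return A list of class `"sd_cross"` with `genotype_freqs` (named
#'   numeric, sums to 1), `male_prop`, `female_prop`.
#' @examples
#' cross(genotype("ZW", reversed = TRUE), genotype("ZW"))
#' cross(genotype("ZW", reversed = TRUE), genotype("ZW"),
#'       viability_config(ww_viable = FALSE))
#' cross(genotype("XX", reversed = TRUE), genotype("XX"))
#' @export
cross <- function(parent1, parent2, viability = viability_config()) {
  stopifnot(inherits(parent1, "sd_genotype"), inherits(parent2, "sd_genotype"),
            inherits(viability, "sd_viability"))
  if (phenotypic_sex(parent1) == phenotypic_sex(parent2))
    stop("invalid cross: parents have the same functional sex (",
         phenotypic_sex(parent1), "); use reversed = TRUE for a ",
         "sex-reversed parent", call. = FALSE)
  if (any(parent1$alleles %in% c("X", "Y")) !=
      any(parent2$alleles %in% c("X", "Y")))
    stop("invalid cross: parents belong to different heterogametic systems",
         call. = FALSE)
  # equal-probability gamete union
  offspring <- character(0)
  for (a in parent1$alleles) for (b in parent2$alleles)
    offspring <- c(offspring, genotype(c(a, b))$label)
  freqs <- table(offspring) / 4
  freqs <- stats::setNames(as.numeric(freqs), names(freqs))
  if (!viability$ww_viable) freqs <- freqs[names(freqs) != "WW"]
  if (!viability$yy_viable) freqs <- freqs[names(freqs) != "YY"]
  if (length(freqs) == 0L)
    stop("no viable offspring genotype under this viability configuration",
         call. = FALSE)
  freqs <- freqs / sum(freqs)
  female <- sum(freqs[names(freqs) %in% c("XX", "ZW", "WW")])
  structure(list(genotype_freqs = freqs,
                 male_prop = 1 - female,
                 female_prop = female),
            class = "sd_cross")
}

#' @export
print.sd_cross <- function(x, ...) {
  cat(sprintf("Expected progeny: %.1f%% male, %.1f%% female\n",
              100 * x$male_prop, 100 * x$female_prop))
  for (g in names(x$genotype_freqs))
    cat(sprintf("  %s: %.4f\n", g, x$genotype_freqs[[g]]))
  invisible(x)
}

#' Progeny of a Wolbachia-infected mother after W loss
#'
#' In lineages where feminizing Wolbachia drove the W chromosome to loss,
#' every individual is genotypically ZZ; offspring that inherit the
#' endosymbiont (probability = maternal transmission rate, ~0.9 in
#' Armadillidium vulgare) develop as functional females, the rest as males.
#' Sex is therefore cytoplasmic and the brood sex ratio equals the
#' transmission rate.
#'
#' @param transmission_rate proportion in `[0, 1]` of offspring inheriting
#'   the endosymbiont.
#' @return An `"sd_cross"` object: all offspring ZZ, `female_prop`
#'   equal to `transmission_rate`.
#' @examples
#' wolbachia_progeny(0.9)
#' @export
wolbachia_progeny <- function(transmission_rate) {
  if (!is.numeric(transmission_rate) || length(transmission_rate) != 1L ||
      is.na(transmission_rate) ||
      transmission_rate < 0 || transmission_rate > 1)
    stop("transmission_rate must be a single number in [0, 1]", call. = FALSE)
  structure(list(genotype_freqs = c(ZZ = 1),
                 male_prop = 1 - transmission_rate,
                 female_prop = transmission_rate),
            class = "sd_cross")
}
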