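# Treatment comparison with star coding, the thresholded Pearson
# correlation network, and the MDA (lipid peroxidation) assay computation.

#' Star coding of a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, otherwise
#' `ns`; thresholds are strict.
#'
#' @param p p-value in \[0, 1\].
#' @return One of `"***"`, `"**"`, `"*"`, `"ns"`.
#' @export
p_stars <- function(p) {
  if (!is_number(p) || p < 0 || p > 1) stopf("p must be in [0, 1]")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Compare control and drought groups for one parameter
#'
#' Two-group comparison of a parameter between label 1 (control) and label 2
#' (drought) rows of a feature table, by Welch's t test (equivalent to
#' one-way ANOVA for two groups under equal variances), with star coding.
#'
#' @param table A [feature_table()] (or any data.frame with a `label` column
#'   and the parameter as a numeric column).
#' @param parameter Column name to test.
#' @param day,genotype Optional subsetting on `day` / `genotype` columns.
#' @return An object of class `significance_result`: list with `parameter`,
#'   `day`, `genotype`, `p_value`, `stars`, and the group means.
#' @export
compare_treatments <- function(table, parameter, day = NULL,
                               genotype = NULL) {
  df <- as.data.frame(table, check.names = FALSE)
  if (!is.null(day)) df <- df[df$day == day, , drop = FALSE]
  if (!is.null(genotype)) df <- df[df$genotype == genotype, , drop = FALSE]
  if (!parameter %in% names(df)) stopf("unknown parameter '%s'", parameter)
  x <- df[[parameter]][df$label == 1L]
  y <- df[[parameter]][df$label == 2L]
  if (length(x) < 2 || length(y) < 2) {
    stopf("each group needs >= 2 samples (got %d and %d)",
          length(x), length(y))
  }
  p <- if (stats::sd(x) == 0 && stats::sd(y) == 0 &&
           isTRUE(all.equal(mean(x), mean(y)))) {
    1
  } else {
    stats::t.test(x, y)$p.value
  }
  structure(list(parameter = parameter, day = day, genotype = genotype,
                 p_value = p, stars = p_stars(p),
                 mean_control = mean(x), mean_drought = mean(y)),
            class = "significance_result")
}

#' Thresholded Pearson correlation network of traits
#'
#' Computes Pearson's r and its t-transform p-value (n - 2 df, no multiple-
#' testing correction) for every pair of traits, keeping edges with
#' `|r| > r_min` and `p < p_max` (both strict). Node categories are
#' assigned from catalogue membership: chlorophyll catalogue names are
#' `kinetic_chl`, multicolor names `multicolor`; remaining traits are looked
#' up in `categories`, defaulting to `morphological` for the standard
#' morphometric names and `physiological` otherwise.
#'
#' @param table Data.frame of numeric traits (non-trait columns such as
#'   `label`, `day`, `genotype`, `sample_id` are ignored).
#' @param trait_subset Optional character vector restricting the traits.
#' @param r_min,p_max Edge thresholds.
#' @param categories Optional named character vector trait -> category.
#' @return An object of class `correlation_network`: list with `nodes`
#'   (data.frame name, category) and `edges` (data.frame source, target, r,
#'   p_value, weight = `|r|`).
#' @export
correlation_network <- function(table, trait_subset = NULL, r_min = 0.40,
                                p_max = 0.01, categories = NULL) {
  df <- as.data.frame(table, check.names = FALSE)
  drop <- c("label", "day", "genotype", "sample_id", "preset")
  df <- df[, setdiff(names(df), drop), drop = FALSE]
  if (!is.null(trait_subset)) {
    missing <- setdiff(trait_subset, names(df))
    if (length(missing)) stopf("unknown trait '%s'", missing[1])
    df <- df[, trait_subset, drop = FALSE]
  }
  df <- df[, vapply(df, is.numeric, logical(1)), drop = FALSE]
  const <- vapply(df, function(x) stats::sd(x, na.rm = TRUE) == 0,
                  logical(1))
  if (any(const)) {
    warnf("excluding constant trait(s): %s",
          paste(names(df)[const], collapse = ", "))
    df <- df[, !const, drop = FALSE]
  }
  nms <- names(df)
  k <- length(nms)
  cat_of <- function(nm) {
    if (nm %in% catalogue_names()) return("kinetic_chl")
    mc <- names(multicolor_parameters(
      c(BF = 1, GF = 1, RF = 1, IrF = 1)))
    if (nm %in% mc) return("multicolor")
    if (!is.null(categories) && nm %in% names(categories)) {
      return(categories[[nm]])
    }
    morph <- c("projected_leaf_area", "rosette_leaf_number",
               "plant_height", "flowering_plant_number")
    if (nm %in% morph) "morphological" else "physiological"
  }
  nodes <- data.frame(name = nms,
                      category = vapply(nms, cat_of, character(1)),
                      stringsAsFactors = FALSE, row.names = NULL)
  src <- character(); tgt <- character()
  rv <- numeric(); pv <- numeric()
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      ok <- stats::complete.cases(df[[i]], df[[j]])
      n <- sum(ok)
      if (n < 3) next
      r <- stats::cor(df[[i]][ok], df[[j]][ok])
      tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      p <- 2 * stats::pt(-abs(tstat), n - 2)
      if (abs(r) > r_min && p < p_max) {
        src <- c(src, nms[i]); tgt <- c(tgt, nms[j])
        rv <- c(rv, r); pv <- c(pv, p)
      }
    }
  }
  edges <- data.frame(source = src, target = tgt, r = rv, p_value = pv,
                      weight = abs(rv), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 r_min = r_min, p_max = p_max),
            class = "correlation_network")
}

#' Convert a correlation network to an igraph object
#'
#' @param net A [correlation_network()].
#' @return An undirected `igraph` graph with `r`, `p_value`, `weight` edge
#'   attributes and a `category` vertex attribute.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Write a correlation network to GraphML and edge-list CSV
#'
#' @param net A [correlation_network()].
#' @param graphml_path,csv_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, graphml_path = NULL, csv_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  }
  if (!is.null(csv_path)) {
    utils::write.csv(net$edges, csv_path, row.names = FALSE)
  }
  invisible(c(graphml_path, csv_path))
}

#' Specify an MDA (TBA) assay measurement
#'
#' Malondialdehyde quantification by the thiobarbituric-acid method:
#' absorbance read at 532 nm with 600 nm turbidity correction, extinction
#' coefficient 155 mM-1 cm-1. Default volumes: 2 mL assay mixture from a
#' 1 mL aliquot of a 5 mL extract of 0.1 g fresh tissue.
#'
#' @param A532,A600 Absorbances.
#' @param epsilon Extinction coefficient, mM-1 cm-1.
#' @param path_cm Optical path length, cm.
#' @param assay_volume_mL,extract_volume_mL,aliquot_mL Volumes, mL.
#' @param fresh_weight_g Tissue fresh weight, g.
#' @return An object of class `mda_assay`.
#' @export
mda_assay <- function(A532, A600, epsilon = 155, path_cm = 1,
                      assay_volume_mL = 2, extract_volume_mL = 5,
                      aliquot_mL = 1, fresh_weight_g = 0.1) {
  vols <- c(epsilon, path_cm, assay_volume_mL, extract_volume_mL,
            aliquot_mL, fresh_weight_g)
  if (any(vols <= 0)) stopf("volumes, weight, epsilon and path must be > 0")
  structure(list(A532 = A532, A600 = A600, epsilon = epsilon,
                 path_cm = path_cm, assay_volume_mL = assay_volume_mL,
                 extract_volume_mL = extract_volume_mL,
                 aliquot_mL = aliquot_mL, fresh_weight_g = fresh_weight_g),
            class = "mda_assay")
}

#' MDA content per gram fresh weight
#'
#' Beer-Lambert concentration of the TBA-MDA chromophore in the assay
#' mixture, `(A532 - A600)/(epsilon * path)` in mM, converted to nmol in the
#' assay volume, scaled from aliquot to full extract, and normalized by
#' fresh weight.
#'
#' @param a An [mda_assay()].
#' @return MDA content in nmol per g fresh weight.
#' @export
mda_content <- function(a) {
  dA <- a$A532 - a$A600
  if (dA < 0) stopf("negative chromophore signal (A532 < A600)")
  conc_mM <- dA / (a$epsilon * a$path_cm)      # mmol/L == umol/mL
  nmol_assay <- conc_mM * a$assay_volume_mL * 1000
  nmol_extract <- nmol_assay * a$extract_volume_mL / a$aliquot_mL
  nmol_extract / a$fresh_weight_g
}
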