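#' Canonical trait names
#'
#' The ten phenotypic traits handled by the package, in canonical column
#' order: leaf area (LA, cm^2), leaf width (LW, cm), leaf length to width
#' ratio (LL_LW), leaf mass per area (LMA, g m^-2), leaf dry matter content
#' (LDMC, mg g^-1), leaf thickness (LT, um), specific stem length
#' (SSL, cm g^-1), sapwood area to twig leaf area ratio (AS_AL, cm^2 m^-2),
#' branch wood density (BWD, g cm^-3) and relative bark thickness
#' (RBT, mm mm^-1).
#'
#' @return Character vector of length 10.
#' @export
trait_names_canon <- function() {
  c("LA", "LW", "LL_LW", "LMA", "LDMC", "LT", "SSL", "AS_AL", "BWD", "RBT")
}

# Exact label matching across sites: Unicode NFC + whitespace trim, no fuzzy
# matching (silent merges are worse than misses).
normalize_label <- function(x) {
  stringi::stri_trans_nfc(trimws(as.character(x)))
}

#' Construct a tree-level trait table
#'
#' A `trait_table` is a data frame with identifier columns `site`, `variety`
#' and `tree` followed by one numeric column per trait, one row per tree.
#' The two-garden study design (which varieties are common to both sites and
#' which are distinct to one) is derived from the observed site x variety
#' occupancy and carried as an attribute.
#'
#' @param df Data frame with columns `site`, `variety`, `tree` and at least
#'   one trait column.
#' @param trait_names Character vector naming the trait columns; defaults to
#'   every non-identifier column.
#' @param validate Run invariant checks (positivity, key uniqueness)?
#'
#' @details Invariants enforced: trait values are numeric and strictly
#'   positive where present (missing values are `NA`, never zero); the
#'   (site, variety, tree) key is unique. A warning is issued for
#'   variety x site cells whose tree count falls outside the 2-3 trees per
#'   variety of the reference design.
#'
#' @return An object of class `trait_table` (a data frame) with attributes
#'   `trait_names` and `design` (see [study_design()]).
#' @export
trait_table <- function(df, trait_names = NULL, validate = TRUE) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  id_cols <- c("site", "variety", "tree")
  missing_cols <- setdiff(id_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in id_cols) df[[col]] <- normalize_label(df[[col]])
  if (is.null(trait_names)) trait_names <- setdiff(names(df), id_cols)
  if (length(trait_names) < 1L) stop("at least one trait column is required")
  unknown <- setdiff(trait_names, names(df))
  if (length(unknown) > 0L) {
    stop("trait column(s) not present: ", paste(unknown, collapse = ", "))
  }
  df <- df[, c(id_cols, trait_names), drop = FALSE]
  for (tr in trait_names) {
    if (!is.numeric(df[[tr]])) {
      val <- suppressWarnings(as.numeric(df[[tr]]))
      bad <- which(is.na(val) & !is.na(df[[tr]]) & df[[tr]] != "" &
                     toupper(df[[tr]]) != "NA")
      if (length(bad) > 0L) {
        stop("non-numeric value in trait '", tr, "' at row ", bad[1L])
      }
      df[[tr]] <- val
    }
  }
  if (validate) {
    key <- paste(df$site, df$variety, df$tree, sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) {
      first <- which(dup)[1L]
      stop("duplicate (site, variety, tree) key: (",
           df$site[first], ", ", df$variety[first], ", ", df$tree[first], ")")
    }
    for (tr in trait_names) {
      nonpos <- which(!is.na(df[[tr]]) & df[[tr]] <= 0)
      if (length(nonpos) > 0L) {
        stop("trait '", tr, "' has non-positive value at row ", nonpos[1L],
             "; trait values must be strictly positive (use NA for missing)")
      }
    }
    counts <- table(paste(df$site, df$variety, sep = "\r"))
    n_odd <- sum(counts < 2L | counts > 3L)
    if (n_odd > 0L) {
      warning(n_odd, " variety x site cell(s) have a tree count outside 2-3")
    }
  }
  structure(df,
            trait_names = trait_names,
            design = study_design(df),
            class = c("trait_table", "data.frame"))
}

#' Study design of a trait table
#'
#' Derives the two-garden design from observed site x variety occupancy:
#' the set of sites, the varieties common to both sites, and the varieties
#' distinct to each site.
#'
#' @param x A `trait_table` or a data frame with `site` and `variety` columns.
#' @return A list with elements `sites`, `common` and `distinct` (a named
#'   list, one character vector per site).
#' @export
study_design <- function(x) {
  sites <- sort(unique(x$site))
  per_site <- lapply(sites, function(s) sort(unique(x$variety[x$site == s])))
  names(per_site) <- sites
  common <- if (length(sites) >= 2L) Reduce(intersect, per_site) else character(0)
  distinct <- lapply(per_site, function(v) setdiff(v, common))
  list(sites = sites, common = sort(common), distinct = distinct)
}

#' @export
print.trait_table <- function(x, ...) {
  d <- attr(x, "design")
  cat("trait_table: ", nrow(x), " trees, ",
      length(unique(x$variety)), " varieties, ",
      length(d$sites), " site(s)\n", sep = "")
  if (length(d$sites) == 2L) {
    cat("  common varieties: ", length(d$common),
        "; distinct: ", paste(vapply(d$distinct, length, 1L), collapse = " + "),
        "\n", sep = "")
  }
  cat("  traits: ", paste(attr(x, "trait_names"), collapse = ", "), "\n", sep = "")
  NextMethod()
  invisible(x)
}

#' Read a tree-level trait table from CSV
#'
#' Reads a UTF-8, comma-separated file with a header row, one row per tree:
#' columns `site`, `variety`, `tree`, then one column per trait. Empty cells
#' and `NA` are read as missing; decimal separator is the dot regardless of
#' locale.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(site = "Garden", variety = "Cultivar", tree = "TreeID")`.
#' @return A [trait_table()].
#' @export
read_trait_table <- function(path, schema = NULL) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = FALSE,
                        na.strings = c("", "NA"), colClasses = "character")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(df)) {
        stop("schema column '", schema[[canon]], "' not found in file")
      }
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  trait_table(df)
}

#' Write a trait table to CSV
#'
#' Inverse of [read_trait_table()]: writes a tidy UTF-8 CSV, one row per
#' tree, identifier columns first then traits in table order. Round-trips
#' exactly for values of up to 15 significant digits.
#'
#' @param table A `trait_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  stopifnot(inherits(table, "trait_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8", na = "NA", quote = TRUE)
  invisible(path)
}

#' Subset a trait table by variety class or site
#'
#' @param table A `trait_table`.
#' @param which `"all"`, `"common"` (varieties present at both sites) or
#'   `"distinct"` (varieties present at a single site).
#' @param site Optional site label to keep; mandatory interpretation for
#'   `which = "distinct"` is "varieties distinct to `site`" when given.
#' @return A `trait_table` with the design recomputed.
#' @export
subset_trait_table <- function(table, which = c("all", "common", "distinct"),
                               site = NULL) {
  stopifnot(inherits(table, "trait_table"))
  which <- match.arg(which)
  d <- attr(table, "design")
  if (!is.null(site)) {
    site <- normalize_label(site)
    if (!site %in% d$sites) stop("unknown site label: ", site)
  }
  keep <- rep(TRUE, nrow(table))
  if (which == "common") {
    keep <- table$variety %in% d$common
  } else if (which == "distinct") {
    if (is.null(site)) {
      keep <- !(table$variety %in% d$common)
    } else {
      keep <- table$variety %in% d$distinct[[site]]
    }
  }
  if (!is.null(site)) keep <- keep & table$site == site
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  trait_table(out, attr(table, "trait_names"), validate = FALSE)
}

#' Variety-level trait means
#'
#' Arithmetic mean per site x variety x trait over trees, ignoring missing
#' values. Cells where every tree is missing a trait are returned as `NA`.
#'
#' @param table A `trait_table`.
#' @return A data frame with columns `site`, `variety`, the per-trait means,
#'   and an attribute `n_trees` (a parallel data frame of the per-trait
#'   number of non-missing trees behind each mean).
#' @export
variety_means <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  traits <- attr(table, "trait_names")
  key <- interaction(table$site, table$variety, drop = TRUE, sep = "\r")
  groups <- levels(key)
  parts <- do.call(rbind, strsplit(groups, "\r", fixed = TRUE))
  out <- data.frame(site = parts[, 1L], variety = parts[, 2L],
                    stringsAsFactors = FALSE)
  ncount <- out
  for (tr in traits) {
    v <- table[[tr]]
    out[[tr]] <- as.numeric(tapply(v, key, function(z) {
      z <- z[!is.na(z)]
      if (length(z) == 0L) NA_real_ else mean(z)
    }))
    ncount[[tr]] <- as.integer(tapply(v, key, function(z) sum(!is.na(z))))
  }
  ord <- order(out$site, out$variety)
  out <- out[ord, , drop = FALSE]
  ncount <- ncount[ord, , drop = FALSE]
  rownames(out) <- rownames(ncount) <- NULL
  attr(out, "n_trees") <- ncount
  out
}

#' Machine-readable design summary
#'
#' @param table A `trait_table`.
#' @param path Optional path; when given, the summary is written as JSON.
#' @return The design list (sites, common and distinct variety sets, tree
#'   and variety counts), invisibly when written to file.
#' @export
design_summary <- function(table, path = NULL) {
  stopifnot(inherits(table, "trait_table"))
  d <- attr(table, "design")
  out <- list(
    sites = d$sites,
    n_trees = nrow(table),
    n_varieties = length(unique(table$variety)),
    common_varieties = d$common,
    distinct_varieties = d$distinct,
    traits = attr(table, "trait_names")
  )
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(out))
  }
  out
}
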