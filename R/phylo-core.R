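# Tree and trait-table data model: Newick I/O, validation, polytomy
# resolution, species reconciliation and per-subset analysis datasets.

#' Read a rooted phylogeny from a Newick file
#'
#' Parses a Newick tree (with branch lengths), validates it and returns an
#' [ape::phylo] object. Trees must have at least two uniquely labelled tips
#' and non-negative branch lengths; polytomies are accepted (see
#' [resolve_polytomies()] for the deterministic bifurcation used before
#' likelihood work).
#'
#' @param path Path to a Newick file, or a Newick string ending in ";".
#' @return A validated `phylo` object. The number of tips is reported via
#'   a message.
#' @export
read_newick <- function(path) {
  txt <- if (is.character(path) && length(path) == 1L && grepl(";\\s*$", path) &&
             !file.exists(path)) {
    path
  } else {
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    # locate the first structurally suspect character for the error message
    bad <- regexpr("[^(),:;[:alnum:]_\\. '\\\"#&<>|-]", txt)
    pos <- if (bad > 0) bad else nchar(txt)
    stop("malformed Newick string (near character ", pos, ")", call. = FALSE)
  }
  validate_tree(tree)
  message(sprintf("read tree with %d tips", ape::Ntip(tree)))
  tree
}

#' Write a phylogeny to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path. If `NULL`, the Newick string is returned
#'   instead of written.
#' @param digits Significant digits for branch lengths (default 12, enough
#'   for round-trip identity within 1e-9).
#' @return Invisibly, the Newick string.
#' @export
write_newick <- function(tree, path = NULL, digits = 12) {
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(path)) writeLines(s, path)
  invisible(s)
}

#' Validate the structural invariants of a phylogeny
#'
#' Checks unique tip labels, >= 2 tips, presence of branch lengths and
#' non-negativity of all lengths. Called by all analysis entry points.
#'
#' @param tree A `phylo` object.
#' @return `tree`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (ape::Ntip(tree) < 2) stop("tree must have at least 2 tips", call. = FALSE)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) {
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("branch lengths must be non-negative and non-missing", call. = FALSE)
  }
  invisible(tree)
}

#' Resolve polytomies to zero-length bifurcations
#'
#' Multifurcations are expanded deterministically (no randomness, ladderized
#' child order) into nested bifurcations joined by zero-length branches.
#' Mk likelihoods and the D statistic are invariant to this resolution
#' because a zero-length branch has an identity transition matrix and a
#' zero-length cherry averages exactly as the original polytomy.
#'
#' @param tree A `phylo` object, possibly with polytomies.
#' @return A strictly bifurcating `phylo` object.
#' @export
resolve_polytomies <- function(tree) {
  validate_tree(tree)
  if (ape::is.binary.phylo(tree)) return(tree)
  out <- ape::multi2di(ape::ladderize(tree), random = FALSE)
  out$edge.length[is.na(out$edge.length)] <- 0
  out
}

# -- trait tables -----------------------------------------------------------

.trait_required_cols <- c("species", "sex", "region", "skin")

#' Read a per-specimen trait table
#'
#' Comma-separated UTF-8 text with a header; one row per
#' species-sex-region record. Required columns: `species`, `sex`
#' (`M`/`F`/`U`), `region` (`head`/`venter`), `skin` (`black`/`non-black`).
#' Optional covariate columns (feather colour category, baldness,
#' dichromatism, mass, coloniality, covered habitat, absolute breeding
#' latitude, UV-B radiance, precipitation, maximum temperature, specimen
#' age, genus, family) are passed through untouched.
#'
#' @param path CSV path.
#' @return A `data.frame` with validated skin/region/sex codings.
#' @export
read_trait_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_trait_table(tab)
}

#' @rdname read_trait_table
#' @param tab A data frame to validate in place of reading a file.
#' @export
validate_trait_table <- function(tab) {
  miss <- setdiff(.trait_required_cols, names(tab))
  if (length(miss)) {
    stop("trait table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(tab$skin), c("black", "non-black"))
  if (length(bad)) {
    stop("skin scores must be binary ('black'/'non-black'); found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(tab$region), c("head", "venter"))
  if (length(bad)) {
    stop("region must be 'head' or 'venter'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tab$sex <- toupper(substr(as.character(tab$sex), 1, 1))
  tab$sex[!tab$sex %in% c("M", "F")] <- "U"
  tab
}

#' Write a trait table or analysis dataset as CSV
#'
#' @param tab Data frame.
#' @param path Output path.
#' @export
write_trait_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reconcile trait-table species against tree tips
#'
#' Species identifiers must resolve against the tip labels of the working
#' phylogeny. Mismatches are never dropped silently: the function returns a
#' reconciliation report listing table species absent from the tree and tree
#' tips without trait data. Congeneric substitution is supported only
#' through an explicit user-supplied alias map (`alias`), never guessed.
#'
#' @param species Character vector of species identifiers from a trait table.
#' @param tree A `phylo` object.
#' @param alias Optional named character vector mapping table names to tip
#'   labels (`c(table_name = "tip_label")`).
#' @return A list with `matched` (renamed species vector), `unmatched_table`,
#'   `unmatched_tree` and `n_aliased`.
#' @export
reconcile_species <- function(species, tree, alias = NULL) {
  sp <- as.character(species)
  n_alias <- 0L
  if (!is.null(alias)) {
    hit <- sp %in% names(alias)
    n_alias <- sum(hit)
    sp[hit] <- unname(alias[sp[hit]])
  }
  list(
    matched         = sp,
    unmatched_table = sort(unique(sp[!sp %in% tree$tip.label])),
    unmatched_tree  = sort(setdiff(tree$tip.label, sp)),
    n_aliased       = n_alias
  )
}

# standard covariates consumed by the regressions; mass and UV are
# log-transformed before standardization
.numeric_covariates <- c("mass_g", "uv_b", "precip", "tmax", "abs_lat",
                         "specimen_age")
.log_covariates <- c("mass_g", "uv_b")
.binary_covariates <- c("bald", "dichromatism", "colonial", "covered")
.feather_levels <- c("brown", "white", "black", "grey", "green", "yellow",
                     "blue", "orange", "purple", "pink", "barred", "bald")

#' Build a one-row-per-species analysis dataset
#'
#' Collapses a per-specimen trait table to one row per species for a given
#' body region and sex priority, resolves species against the tree, and
#' standardizes covariates. A species is scored black if at least one of its
#' specimens (for the chosen records) was observed with black skin. When
#' both sexes were scored, records of the priority sex are used; the other
#' sex is the fallback when the priority sex is absent.
#'
#' Numeric covariates are standardized to mean 0 / sd 1 after
#' log-transforming mass and UV-B radiance; rows with missing covariates are
#' dropped with a logged count (no imputation). Feather colour enters as
#' one-hot indicators with `brown` as the reference level.
#'
#' @param tab Trait table (see [read_trait_table()]).
#' @param region `"head"` or `"venter"`.
#' @param sex_priority `"male"` or `"female"`.
#' @param tree A `phylo` object; species are pruned to its tips.
#' @param alias Optional alias map passed to [reconcile_species()].
#' @param covariates Character vector of numeric/binary covariate columns to
#'   keep (defaults to every recognised column present).
#' @return A `data.frame` with `species`, binary response `y`, standardized
#'   covariates, and attributes `subset` (e.g. `"head-male-priority"`),
#'   `reconciliation`, and `n_dropped_missing`.
#' @export
build_analysis_dataset <- function(tab, region = c("head", "venter"),
                                   sex_priority = c("male", "female"),
                                   tree, alias = NULL, covariates = NULL) {
  region <- match.arg(region)
  sex_priority <- match.arg(sex_priority)
  tab <- validate_trait_table(tab)
  validate_tree(tree)

  tab <- tab[tab$region == region, , drop = FALSE]
  if (!nrow(tab)) stop("no records for region '", region, "'", call. = FALSE)
  pri <- if (sex_priority == "male") "M" else "F"

  rec <- reconcile_species(tab$species, tree, alias)
  tab$species <- rec$matched
  tab <- tab[tab$species %in% tree$tip.label, , drop = FALSE]
  if (!nrow(tab)) {
    stop("no trait-table species match the tree tips", call. = FALSE)
  }

  rows <- lapply(split(tab, tab$species), function(d) {
    use <- d[d$sex == pri, , drop = FALSE]
    if (!nrow(use)) use <- d           # fallback: whatever records exist
    out <- use[1, , drop = FALSE]
    out$y <- as.integer(any(use$skin == "black"))
    out
  })
  ds <- do.call(rbind, rows)
  rownames(ds) <- NULL

  keep_num <- intersect(.numeric_covariates, names(ds))
  keep_bin <- intersect(.binary_covariates, names(ds))
  if (!is.null(covariates)) {
    keep_num <- intersect(keep_num, covariates)
    keep_bin <- intersect(keep_bin, covariates)
  }

  # one-hot feather colours against the brown reference
  if ("feather" %in% names(ds)) {
    lev <- intersect(.feather_levels, unique(ds$feather))
    for (l in setdiff(lev, "brown")) {
      ds[[paste0("feather_", l)]] <- as.integer(ds$feather == l)
    }
  }

  cc_cols <- c(keep_num, keep_bin)
  n_drop <- 0L
  if (length(cc_cols)) {
    ok <- stats::complete.cases(ds[, cc_cols, drop = FALSE])
    n_drop <- sum(!ok)
    if (n_drop) message(sprintf("dropped %d species with missing covariates",
                                n_drop))
    ds <- ds[ok, , drop = FALSE]
  }

  for (v in keep_num) {
    x <- ds[[v]]
    if (v %in% .log_covariates) {
      if (any(x <= 0, na.rm = TRUE)) {
        stop("covariate '", v, "' must be positive for log transform",
             call. = FALSE)
      }
      x <- log(x)
    }
    ds[[v]] <- standardize(x)
  }

  ds <- ds[order(ds$species), , drop = FALSE]
  attr(ds, "subset") <- paste0(region, "-", sex_priority, "-priority")
  attr(ds, "reconciliation") <- rec
  attr(ds, "n_dropped_missing") <- n_drop
  ds
}

#' Standardize a numeric vector to mean 0 and sd 1
#'
#' @param x Numeric vector.
#' @return Standardized vector; constant input raises an error.
#' @export
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant column",
                                    call. = FALSE)
  (x - mean(x)) / s
}

# named 0/1 trait vector aligned to the tree tips; shared by the Mk,
# mapping and D machinery
.align_trait <- function(tree, y) {
  if (is.null(names(y))) stop("trait vector must be named by tip label",
                              call. = FALSE)
  miss <- setdiff(tree$tip.label, names(y))
  if (length(miss)) {
    stop("tips missing from trait: ", paste(utils::head(miss, 5),
         collapse = ", "), if (length(miss) > 5) ", ..." else "",
         call. = FALSE)
  }
  y <- y[tree$tip.label]
  if (!all(y %in% c(0, 1))) stop("trait must be binary 0/1", call. = FALSE)
  as.integer(y)
}
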