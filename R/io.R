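# Reading and validating the survey tables and phylogenies.
#
# Canonical units follow the reporting convention of leaf-ionomics surveys:
# N and P in mg g^-1, the trace elements (K, Ca, Cu, Zn, Mn, Fe, Mg) in
# mg kg^-1. A config block bridges whatever column names / units the source
# file uses, so unit mistakes fail loudly instead of silently scaling by 1000.

LEAF_ELEMENTS <- c("N", "P", "K", "Ca", "Cu", "Zn", "Mn", "Fe", "Mg")
LEAF_ROLES <- c("target", "positive_ref", "negative_ref")

#' Configuration for reading a leaf-chemistry table
#'
#' Maps the columns and units of a delimited leaf-chemistry file onto the
#' canonical layout used throughout the package: one row per sampled
#' individual with `site_id`, `region`, `species`, `genus`, `role`
#' (`target`, `positive_ref` or `negative_ref`), `replicate`, `leaf_age`
#' (`mature`/`young`) and element concentrations `N`, `P` (mg g⁻¹) and
#' `K`, `Ca`, `Cu`, `Zn`, `Mn`, `Fe`, `Mg` (mg kg⁻¹).
#'
#' @param columns Named character vector mapping canonical column names to
#'   the names used in the file, e.g. `c(site_id = "Site", Mn = "Mn_ppm")`.
#'   Unmapped canonical names are assumed to appear verbatim.
#' @param unit_scale Named numeric vector of multiplicative factors applied
#'   to element columns after reading, to convert the file's units into the
#'   canonical units (e.g. `c(P = 1000)` if the file stores P in g g⁻¹... the
#'   factor is whatever turns the file's unit into mg g⁻¹ / mg kg⁻¹).
#' @param aliases Named character vector of taxon synonyms applied to the
#'   `species` column (name = as written in the file, value = accepted name).
#'   Used for post-collection taxonomic revisions; matching is exact after
#'   whitespace/underscore normalisation.
#' @return A list of class `leaf_config`.
#' @export
#' @examples
#' cfg <- leaf_config(columns = c(site_id = "Site"), unit_scale = c(Mn = 1))
leaf_config <- function(columns = character(), unit_scale = numeric(),
                        aliases = character()) {
  if (length(columns) && is.null(names(columns)))
    abort("`columns` must be a named character vector (canonical = file).")
  if (length(unit_scale) && (is.null(names(unit_scale)) ||
      !all(names(unit_scale) %in% LEAF_ELEMENTS)))
    abort("`unit_scale` names must be element columns (N, P, K, Ca, Cu, Zn, Mn, Fe, Mg).")
  structure(list(columns = columns, unit_scale = unit_scale, aliases = aliases),
            class = "leaf_config")
}

#' Example configuration mirroring the packaged survey design
#'
#' Encodes the reference-species choices used in eucalypt Mn surveys:
#' Proteaceae (*Banksia*, *Persoonia*) as positive references,
#' *Xanthorrhoea*, *Acacia*, *Macrozamia* or young eucalypt leaves as
#' negative references. Returned as a [leaf_config()] with documented
#' aliases; the `role` column of the input remains authoritative.
#'
#' @return A `leaf_config`.
#' @export
paper_like_config <- function() {
  leaf_config(aliases = c(Eucalyptus_signata = "Eucalyptus_racemosa"))
}

.read_delim_checked <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

.apply_columns <- function(df, columns) {
  for (canon in names(columns)) {
    file_col <- columns[[canon]]
    if (!file_col %in% names(df))
      abort(paste0("configured column `", file_col, "` (for `", canon,
                   "`) not found in file"))
    names(df)[names(df) == file_col] <- canon
  }
  df
}

#' Read a leaf-chemistry table
#'
#' Reads a delimited (CSV, RFC-4180) leaf-chemistry file into the canonical
#' one-row-per-individual tibble, validating every row. Mandatory columns
#' (after config mapping): `site_id` (or `site`), `species`, `genus`,
#' `role`, and at least the `Mn` element column. Optional: `region`,
#' `replicate` (auto-numbered within site x species when absent),
#' `leaf_age` (defaults to `"mature"`).
#'
#' @param path Path to the file.
#' @param config A [leaf_config()].
#' @return A tibble of validated leaf samples.
#' @export
read_leaf_table <- function(path, config = leaf_config()) {
  df <- .read_delim_checked(path)
  df <- .apply_columns(df, config$columns)
  if (!"site_id" %in% names(df) && "site" %in% names(df))
    names(df)[names(df) == "site"] <- "site_id"

  required <- c("site_id", "species", "genus", "role", "Mn")
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort(paste0("leaf table format error: missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))

  df <- as_tibble(df)
  df$species <- normalize_taxon(df$species)
  if (length(config$aliases)) {
    al <- setNames(as.character(config$aliases),
                   normalize_taxon(names(config$aliases)))
    hit <- df$species %in% names(al)
    df$species[hit] <- normalize_taxon(al[df$species[hit]])
  }
  if (!"region" %in% names(df)) df$region <- NA_character_
  if (!"leaf_age" %in% names(df)) df$leaf_age <- "mature"
  df$leaf_age[is.na(df$leaf_age)] <- "mature"

  bad_role <- which(!df$role %in% LEAF_ROLES)
  if (length(bad_role))
    abort(paste0("leaf table validation error: row(s) ",
                 paste(head(bad_role, 5), collapse = ", "),
                 ": role must be one of ", paste(LEAF_ROLES, collapse = ", ")))
  bad_age <- which(!df$leaf_age %in% c("mature", "young"))
  if (length(bad_age))
    abort(paste0("leaf table validation error: row(s) ",
                 paste(head(bad_age, 5), collapse = ", "),
                 ": leaf_age must be 'mature' or 'young'"))

  elements <- intersect(LEAF_ELEMENTS, names(df))
  for (el in elements) {
    df[[el]] <- as.numeric(df[[el]])
    scale <- config$unit_scale[el]
    if (!is.na(scale) && length(scale)) df[[el]] <- df[[el]] * as.numeric(scale)
    bad <- which(!is.na(df[[el]]) & df[[el]] < 0)
    if (length(bad))
      abort(paste0("leaf table validation error: negative ", el,
                   " concentration in row(s) ",
                   paste(head(bad, 5), collapse = ", ")))
  }

  if (!"replicate" %in% names(df)) {
    df <- df |>
      group_by(.data$site_id, .data$species) |>
      mutate(replicate = row_number()) |>
      ungroup()
  }
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate) | df$replicate < 1))
    abort("leaf table validation error: replicate must be an integer >= 1")
  dup <- df |> count(.data$site_id, .data$species, .data$replicate) |>
    filter(.data$n > 1)
  if (nrow(dup))
    abort(paste0("leaf table validation error: duplicate (site, species, replicate): ",
                 paste(head(paste(dup$site_id, dup$species, dup$replicate), 3),
                       collapse = "; ")))

  df |>
    select(any_of(c("site_id", "region", "species", "genus", "role",
                    "replicate", "leaf_age", LEAF_ELEMENTS)))
}

#' Read a soil-chemistry table
#'
#' One row per sampling location (one or more per site). Expected columns:
#' `site_id` (or `site`), `pH_water`, `pH_cacl2`, `ec` (µS cm⁻¹),
#' `olsen_p` and `water_p` (mg kg⁻¹), plus any number of `total_*` element
#' columns in mg kg⁻¹ (e.g. `total_P`, `total_Mn`).
#'
#' @param path Path to the file.
#' @return A validated tibble.
#' @export
read_soil_table <- function(path) {
  df <- .read_delim_checked(path)
  if (!"site_id" %in% names(df) && "site" %in% names(df))
    names(df)[names(df) == "site"] <- "site_id"
  if (!"site_id" %in% names(df))
    abort("soil table format error: missing mandatory column site_id")
  for (col in intersect(c("pH_water", "pH_cacl2"), names(df))) {
    bad <- which(!is.na(df[[col]]) & (df[[col]] <= 0 | df[[col]] >= 14))
    if (length(bad))
      abort(paste0("soil table validation error: ", col,
                   " outside (0, 14) in row(s) ",
                   paste(head(bad, 5), collapse = ", ")))
  }
  if ("olsen_p" %in% names(df) && any(df$olsen_p < 0, na.rm = TRUE))
    abort("soil table validation error: negative olsen_p")
  as_tibble(df)
}

#' Read a Newick tree
#'
#' Parses a rooted, branch-length-annotated Newick string (or file) into an
#' `ape::phylo` object, rejecting malformed input and duplicate tip labels.
#'
#' @param x A Newick string, or a path to a file containing one.
#' @return A `phylo` object.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  is_path <- !grepl("\\(", x) && file.exists(x)
  txt <- if (is_path) paste(readLines(x, warn = FALSE), collapse = "") else x
  if (!grepl(";\\s*$", txt)) txt <- paste0(txt, ";")
  n_open <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  n_close <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (n_open != n_close)
    abort("Newick parse error: unbalanced parentheses")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    abort("Newick parse error: not a well-formed tree")
  tree$tip.label <- normalize_taxon(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    abort(paste0("Newick parse error: duplicate tip label(s): ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  if (is.null(tree$edge.length))
    abort("Newick parse error: tree has no branch lengths")
  if (any(tree$edge.length < 0))
    abort("Newick parse error: negative branch length")
  tree
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL, digits = 12) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Prune a phylogeny to a set of tips
#'
#' Keeps exactly the requested tips, collapsing degree-2 internal nodes by
#' summing branch lengths, so that all pairwise path lengths among kept tips
#' are preserved. Tip matching is exact after whitespace/underscore
#' normalisation; no fuzzy matching.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to keep (at least two).
#' @return The pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- normalize_taxon(keep)
  labs <- normalize_taxon(tree$tip.label)
  missing <- setdiff(keep, labs)
  if (length(missing))
    abort(paste0("tip label(s) not in tree: ", paste(missing, collapse = ", ")))
  if (length(unique(keep)) < 2)
    abort("need at least two tips to keep")
  tree$tip.label <- labs
  ape::keep.tip(tree, keep)
}

#' Report whether a tree is ultrametric
#'
#' Ultrametricity is checked and reported, never enforced: trees are used
#' as given.
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance on root-to-tip depth variation.
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  diff(range(d)) <= tol * max(d, 1)
}
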