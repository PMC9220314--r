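#' Read a plot-by-function measurement table
#'
#' Reads a delimited text file with plot identifiers in the first column and
#' one numeric column per soil function, on each function's native scale.
#' Values are never imputed: any missing or non-numeric cell is an error, with
#' the offending row and column named.
#'
#' @param path Path to a delimited text file. The header row holds function
#'   names; the first column holds plot ids.
#' @param delim Field delimiter, `"\t"` (default) or `","`.
#' @param require_default If `TRUE`, require all ten canonical functions
#'   ([soil_function_names()]) to be present.
#' @return A tibble with a `plot_id` column and one numeric column per
#'   function, preserving file order.
#' @seealso [write_function_matrix()], [zscore_standardize()]
#' @export
read_function_matrix <- function(path, delim = "\t", require_default = FALSE) {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  if (ncol(raw) < 2) abort("Function matrix file needs >= 2 columns.")
  names(raw)[1] <- "plot_id"
  raw$plot_id <- as.character(raw$plot_id)
  for (fn in setdiff(names(raw), "plot_id")) {
    v <- raw[[fn]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num))
      if (length(bad) > 0) {
        abort(paste0("Non-numeric cell in function '", fn, "', plot '",
                     raw$plot_id[bad[1]], "' (value '", v[bad[1]], "')."))
      }
      raw[[fn]] <- num
    }
    if (anyNA(raw[[fn]])) {
      bad <- which(is.na(raw[[fn]]))[1]
      abort(paste0("Missing value in function '", fn, "', plot '",
                   raw$plot_id[bad], "'."))
    }
  }
  validate_function_matrix(raw, require_default = require_default)
  tibble::as_tibble(raw)
}

#' Write a plot-by-function table to delimited text
#'
#' @param fm Function matrix tibble (see [read_function_matrix()]).
#' @param path Output file path.
#' @param delim Field delimiter.
#' @param comments Optional character vector written as `# `-prefixed header
#'   lines (used by [run_pipeline()] to record parameters).
#' @return `path`, invisibly.
#' @export
write_function_matrix <- function(fm, path, delim = "\t", comments = NULL) {
  validate_function_matrix(fm)
  write_commented_delim(fm, path, delim = delim, comments = comments)
}

#' Read a BIOM-style tab-separated OTU count table
#'
#' Reads the classic BIOM TSV dialect: rows are OTUs, columns are samples,
#' and the header may begin with `#OTU ID` (a leading `# Constructed from
#' biom file` line is skipped). The returned table is always in the package's
#' canonical orientation, samples x OTUs; use `orientation =
#' "samples_as_rows"` for files already transposed.
#'
#' @param path Path to a delimited text file of non-negative integer counts.
#' @param delim Field delimiter, `"\t"` (default) or `","`.
#' @param orientation `"otus_as_rows"` (BIOM-style default) or
#'   `"samples_as_rows"`.
#' @param domain Optional domain tag (`"bacteria"` or `"fungi"`), stored as
#'   the `"domain"` attribute.
#' @return A tibble with a `sample_id` column and one integer column per OTU.
#'   Every sample must have a positive total count.
#' @export
read_otu_table <- function(path, delim = "\t",
                           orientation = c("otus_as_rows", "samples_as_rows"),
                           domain = NULL) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  # Classic BIOM TSV: skip pure comment lines but keep a '#OTU ID' header.
  is_comment <- startsWith(lines, "#") & !startsWith(lines, "#OTU ID")
  lines <- lines[!is_comment]
  if (length(lines) < 2) abort("OTU table file has no data rows.")
  fields <- strsplit(lines, delim, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1) {
    abort(paste0("Ragged OTU table: rows have ", paste(unique(widths),
                 collapse = ", "), " fields."))
  }
  header <- fields[[1]]
  body <- fields[-1]
  row_ids <- vapply(body, `[[`, character(1), 1)
  col_ids <- header[-1]
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(body, `[`, -1))),
           nrow = length(body), byrow = TRUE)
  )
  if (anyNA(vals)) abort("Non-numeric count in OTU table.")
  if (orientation == "otus_as_rows") {
    m <- t(vals)
    rownames(m) <- col_ids
    colnames(m) <- row_ids
  } else {
    m <- vals
    rownames(m) <- row_ids
    colnames(m) <- col_ids
  }
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.integer))
  out <- tibble::add_column(out, sample_id = rownames(m), .before = 1)
  validate_otu_table(out)
  if (!is.null(domain)) {
    attr(out, "domain") <- match.arg(domain, c("bacteria", "fungi"))
  }
  out
}

#' Write an OTU count table as BIOM-style TSV
#'
#' Writes in the classic dialect (rows = OTUs, `#OTU ID` header) so the file
#' round-trips through [read_otu_table()] exactly.
#'
#' @inheritParams write_function_matrix
#' @param otu OTU table tibble in canonical samples x OTUs orientation.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(otu, path, delim = "\t", comments = NULL) {
  validate_otu_table(otu)
  m <- t(otu_matrix(otu))
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  out <- tibble::add_column(out, `#OTU ID` = rownames(m), .before = 1)
  write_commented_delim(out, path, delim = delim, comments = comments)
}

#' Read plot metadata (site, diversity level, biomass)
#'
#' Expects columns `plot_id`, `site_id`, `diversity_level` (exactly two
#' levels, by convention `low`/`high`), `agb` and `bgb` (above-/below-ground
#' biomass, g m^-2). The ratio `bgb_agb_ratio` is recomputed from `bgb/agb`.
#'
#' @inheritParams read_function_matrix
#' @return A tibble with one row per plot; `diversity_level` is a factor with
#'   levels `low`, `high` where those labels are used.
#' @export
read_plot_metadata <- function(path, delim = "\t") {
  md <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  need <- c("plot_id", "site_id", "diversity_level", "agb", "bgb")
  missing <- setdiff(need, names(md))
  if (length(missing) > 0) {
    abort(paste0("Plot metadata is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  md$plot_id <- as.character(md$plot_id)
  if (anyDuplicated(md$plot_id)) {
    abort("Duplicate plot ids in metadata.")
  }
  lev <- unique(as.character(md$diversity_level))
  if (length(lev) != 2) {
    abort(paste0("`diversity_level` must have exactly two levels, found: ",
                 paste(lev, collapse = ", ")))
  }
  ord <- if (setequal(lev, c("low", "high"))) c("low", "high") else sort(lev)
  md$diversity_level <- factor(as.character(md$diversity_level), levels = ord)
  if (any(!is.finite(md$agb)) || any(!is.finite(md$bgb))) {
    abort("`agb`/`bgb` must be finite.")
  }
  if (any(md$agb <= 0)) abort("`agb` must be positive to form BGB:AGB.")
  md$bgb_agb_ratio <- md$bgb / md$agb
  tibble::as_tibble(md)
}

#' Read an OTU-to-guild annotation table
#'
#' Two-column delimited text mapping fungal OTU ids to trophic guilds
#' (`pathotroph`, `saprotroph`, `symbiotroph`, or `unassigned`), e.g. an
#' exported FUNGuild-style lookup. OTUs absent from the map are treated as
#' `unassigned` downstream.
#'
#' @inheritParams read_function_matrix
#' @return A tibble with columns `otu_id`, `guild`.
#' @export
read_guild_map <- function(path, delim = "\t") {
  gm <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(gm) < 2) abort("Guild map needs two columns: otu_id, guild.")
  names(gm)[1:2] <- c("otu_id", "guild")
  gm$otu_id <- as.character(gm$otu_id)
  gm$guild <- as.character(gm$guild)
  bad <- setdiff(unique(gm$guild), guild_levels())
  if (length(bad) > 0) {
    abort(paste0("Unknown guild label(s): ", paste(bad, collapse = ", "),
                 ". Allowed: ", paste(guild_levels(), collapse = ", ")))
  }
  tibble::as_tibble(gm[c("otu_id", "guild")])
}

guild_levels <- function() c("pathotroph", "saprotroph", "symbiotroph", "unassigned")

# Deterministic delimited writer used for all pipeline outputs: optional
# '# '-prefixed header comments, then readr-formatted body.
write_commented_delim <- function(df, path, delim = "\t", comments = NULL) {
  body <- readr::format_delim(df, delim = delim, eol = "\n")
  header <- if (length(comments) > 0) paste0("# ", comments) else character(0)
  writeLines(c(header, sub("\n$", "", body)), path, sep = "\n")
  invisible(path)
}
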