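#' The table of known GO evidence codes
#'
#' Shipped with the package as a versioned data file
#' (`extdata/evidence_codes.tsv`). Codes are grouped into classes:
#' experimental, high-throughput, phylogenetic, computational, author,
#' curator and electronic.
#'
#' @return Tibble with columns `code`, `class`, `description`.
#' @export
known_evidence_codes <- function() {
  path <- system.file("extdata", "evidence_codes.tsv", package = "phyloanno",
                      mustWork = TRUE)
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Evidence-class configuration for inference
#'
#' Controls which evidence codes count as usable experimental support for
#' placing gains. High-throughput (HTP) codes are excluded by default:
#' high-throughput experiments carry a high false-positive rate (nominally
#' ~1% per study, additive as more datasets are integrated), particularly
#' for subcellular localization, so they are quarantined unless the curator
#' opts in. The HTP code set itself is configurable because the boundary of
#' "high throughput" is policy, not algorithm.
#'
#' @param experimental_codes Codes usable as direct experimental support.
#' @param htp_codes High-throughput codes, excluded from support unless
#'   `htp_usable_for_inference` is `TRUE`.
#' @param htp_usable_for_inference Allow HTP codes as gain support?
#' @return An object of class `evidence_config`.
#' @export
evidence_config <- function(experimental_codes = c("EXP", "IDA", "IPI", "IMP",
                                                   "IGI", "IEP"),
                            htp_codes = c("HDA", "HMP", "HGI", "HEP", "HTP"),
                            htp_usable_for_inference = FALSE) {
  if (length(intersect(experimental_codes, htp_codes))) {
    abort("experimental_codes and htp_codes must be disjoint",
          class = "phyloanno_config_error")
  }
  structure(list(experimental_codes = experimental_codes,
                 htp_codes = htp_codes,
                 htp_usable_for_inference = isTRUE(htp_usable_for_inference)),
            class = "evidence_config")
}

gaf_columns <- c("db", "object_id", "symbol", "qualifier", "go_id",
                 "references", "evidence_code", "with_from", "aspect",
                 "object_name", "synonyms", "object_type", "taxon", "date",
                 "assigned_by", "extension", "gene_product_form")

#' An empty annotation table
#'
#' @return A zero-row GAF record tibble with the standard 17 columns plus
#'   the derived `negated` flag; `references` and `with_from` are
#'   list-columns of character vectors.
#' @export
empty_gaf <- function() {
  out <- tibble(
    db = character(), object_id = character(), symbol = character(),
    qualifier = character(), go_id = character(),
    references = list(), evidence_code = character(), with_from = list(),
    aspect = character(), object_name = character(), synonyms = character(),
    object_type = character(), taxon = character(), date = character(),
    assigned_by = character(), extension = character(),
    gene_product_form = character(), negated = logical()
  )
  out
}

#' Construct GAF annotation records
#'
#' Convenience row builder used by the simulator and tests; vectorized over
#' its arguments.
#'
#' @param db,object_id,symbol,go_id,evidence_code,aspect,taxon Core fields.
#' @param qualifier GAF qualifier string (`"NOT"` marks negation).
#' @param references Character vector (recycled) or list of character
#'   vectors of citation ids.
#' @param with_from As `references`.
#' @param date,assigned_by Provenance fields.
#' @return A GAF record tibble.
#' @export
gaf_record <- function(db, object_id, go_id, evidence_code,
                       symbol = object_id, qualifier = "",
                       references = "PMID:0000001", with_from = character(),
                       aspect = "P", taxon = "taxon:0", date = "20260101",
                       assigned_by = "phylo-annot") {
  n <- max(length(object_id), length(go_id), length(evidence_code))
  as_list_col <- function(x, n) {
    if (!is.list(x)) x <- list(x)
    rep_len(x, n)
  }
  tibble(
    db = rep_len(db, n), object_id = rep_len(object_id, n),
    symbol = rep_len(symbol, n), qualifier = rep_len(qualifier, n),
    go_id = rep_len(go_id, n),
    references = as_list_col(references, n),
    evidence_code = rep_len(evidence_code, n),
    with_from = as_list_col(with_from, n),
    aspect = rep_len(aspect, n), object_name = rep_len("", n),
    synonyms = rep_len("", n), object_type = rep_len("protein", n),
    taxon = rep_len(taxon, n), date = rep_len(date, n),
    assigned_by = rep_len(assigned_by, n), extension = rep_len("", n),
    gene_product_form = rep_len("", n),
    negated = grepl("(^|\\|)NOT($|\\|)", rep_len(qualifier, n))
  )
}

#' Read a GAF 2.1/2.2 annotation file
#'
#' One record per non-comment line. The qualifier column is parsed:
#' `NOT` alone or as part of a piped qualifier (`NOT|involved_in`) sets the
#' `negated` flag. Pipe-separated `references` and `with_from` fields are
#' split into character-vector list-columns.
#'
#' @param x Path to a GAF file, or the document itself.
#' @return A GAF record tibble (see [empty_gaf()] for the columns).
#' @details The header must declare `!gaf-version: 2.1` or `2.2`; any other
#'   version is a format error. A line with the wrong column count is an
#'   error naming the line number.
#' @export
read_gaf <- function(x) {
  lines <- input_lines(x)
  lines <- sub("\r$", "", lines)
  header <- grep("^!gaf-version:", lines, value = TRUE)
  if (length(header) == 0) {
    abort("missing !gaf-version header", class = "phyloanno_format_error")
  }
  version <- trimws(sub("^!gaf-version:", "", header[1]))
  if (!(version %in% c("2.1", "2.2"))) {
    abort(sprintf("unsupported gaf-version: %s", version),
          class = "phyloanno_format_error")
  }
  data_idx <- which(!startsWith(lines, "!") & nzchar(trimws(lines)))
  if (length(data_idx) == 0) return(empty_gaf())
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  # trailing empty optional columns may be omitted by some writers; GAF is
  # 17 columns, with 15..17 accepted on read (cols 16-17 optional-empty)
  bad <- which(nf < 15 | nf > 17)
  if (length(bad)) {
    abort(sprintf("line %d has %d columns (expected 17)",
                  data_idx[bad[1]], nf[bad[1]]),
          class = "phyloanno_format_error")
  }
  fields <- lapply(fields, function(f) c(f, rep("", 17 - length(f))))
  m <- do.call(rbind, fields)
  colnames(m) <- gaf_columns
  out <- as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
  split_pipe <- function(v) {
    lapply(strsplit(v, "|", fixed = TRUE), function(p) p[nzchar(p)])
  }
  out$references <- split_pipe(out$references)
  out$with_from <- split_pipe(out$with_from)
  quals <- strsplit(out$qualifier, "|", fixed = TRUE)
  out$negated <- vapply(quals, function(q) "NOT" %in% q, logical(1))
  out
}

validate_gaf <- function(records) {
  checks <- list(
    go_id = all(is_go_id(records$go_id)),
    evidence_code = all(records$evidence_code %in% known_evidence_codes()$code),
    references = all(lengths(records$references) > 0),
    aspect = all(records$aspect %in% c("F", "P", "C")),
    object_id = all(nzchar(records$object_id))
  )
  bad <- names(checks)[!unlist(checks)]
  if (length(bad)) {
    abort(sprintf("invalid GAF record field(s): %s", paste(bad, collapse = ", ")),
          class = "phyloanno_validation_error")
  }
  invisible(records)
}

#' Write annotations as GAF 2.1
#'
#' Emits a tab-separated GAF 2.1 document (17 columns), records sorted by
#' (`object_id`, `go_id`, `evidence_code`) for byte-stable output. The
#' 2.1 dialect (qualifier optional) is used for output because it maximizes
#' reader compatibility; [read_gaf()] accepts both 2.1 and 2.2.
#'
#' @param records A GAF record tibble.
#' @param file Optional output path.
#' @param extra_header Optional character vector of additional `!` comment
#'   lines (e.g. provenance) appended after the version line.
#' @return The document as a string, invisibly when `file` is set.
#' @export
write_gaf <- function(records, file = NULL, extra_header = character()) {
  if (nrow(records)) validate_gaf(records)
  ord <- order(records$object_id, records$go_id, records$evidence_code)
  records <- records[ord, , drop = FALSE]
  qual <- ifelse(records$negated & !grepl("(^|\\|)NOT($|\\|)", records$qualifier),
                 ifelse(nzchar(records$qualifier),
                        paste0("NOT|", records$qualifier), "NOT"),
                 records$qualifier)
  join_pipe <- function(l) vapply(l, paste, character(1), collapse = "|")
  cols <- list(
    records$db, records$object_id, records$symbol, qual, records$go_id,
    join_pipe(records$references), records$evidence_code,
    join_pipe(records$with_from), records$aspect, records$object_name,
    records$synonyms, records$object_type, records$taxon, records$date,
    records$assigned_by, records$extension, records$gene_product_form
  )
  body <- if (nrow(records)) do.call(paste, c(cols, sep = "\t")) else character()
  lines <- c("!gaf-version: 2.1", extra_header, body)
  if (!is.null(file)) {
    write_lines_file(lines, file)
    return(invisible(paste(lines, collapse = "\n")))
  }
  paste(lines, collapse = "\n")
}

#' Split annotations into inference-usable and excluded sets
#'
#' Usable records are the non-negated records whose evidence code is in the
#' configured experimental set (plus the HTP set when
#' `htp_usable_for_inference` is on). Everything else is excluded with a
#' reason: `negated` (a NOT-qualified record whose code would otherwise be
#' usable — these are retained and routed to the negative-evidence stream,
#' where they place losses), `htp` (high-throughput code under the default
#' policy), or `non_experimental` (ISS/IEA/TAS/IC and the like, which are
#' never usable for gain support: phylogenetic inference must rest on
#' experiment).
#'
#' @param records A GAF record tibble.
#' @param config An [evidence_config()].
#' @return A list with tibbles `usable` and `excluded`; `excluded` carries
#'   an extra `exclusion_reason` column. The two partition the input.
#' @export
filter_experimental <- function(records, config = evidence_config()) {
  usable_codes <- config$experimental_codes
  if (config$htp_usable_for_inference) {
    usable_codes <- c(usable_codes, config$htp_codes)
  }
  in_usable <- records$evidence_code %in% usable_codes
  is_usable <- in_usable & !records$negated
  reason <- ifelse(in_usable & records$negated, "negated",
            ifelse(records$evidence_code %in% config$htp_codes, "htp",
                   "non_experimental"))
  excluded <- records[!is_usable, , drop = FALSE]
  excluded$exclusion_reason <- reason[!is_usable]
  list(usable = records[is_usable, , drop = FALSE], excluded = excluded)
}
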