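# Tag extraction and counting from SAGE concatemer reads.
#
# A concatemer is a string of ditags separated by the anchoring-enzyme site
# (CATG for NlaIII).  A ditag is two tags ligated tail-to-tail: the first
# tag_len bases read forward, the last tag_len bases are the reverse
# complement of the second tag.  Ditags between tag_len and 2*tag_len long
# yield two overlapping tags (the variable BsmFI cut makes short ditags
# legitimate); anything shorter is rejected.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences over A/C/G/T/N.
#' @return character vector of the same length.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  flipped <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

.check_dna <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty DNA string", call. = FALSE)
  }
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L) {
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         substr(bad, 1L, 10L), call. = FALSE)
  }
  invisible(sequence)
}

#' Extract ditags from a concatemer read
#'
#' Returns the maximal substrings strictly between consecutive occurrences of
#' the anchoring site whose lengths fall within \code{[min_len, max_len]}.
#' Segments outside the bounds (including zero-length segments between
#' adjacent sites) are discarded.  Order of appearance is preserved.
#'
#' @param sequence a single DNA string over A/C/G/T/N.
#' @param min_len,max_len inclusive ditag length bounds.  Defaults 20 and 26
#'   follow the standard SAGE convention for 10-bp tags.
#' @param anchor anchoring enzyme recognition site, default \code{"CATG"}
#'   (NlaIII).
#' @return character vector of ditag sequences (possibly empty).
#' @examples
#' extract_ditags("CATGAAAAAAAAAATTTTTTTTTTCATG")
#' @export
extract_ditags <- function(sequence, min_len = 20L, max_len = 26L,
                           anchor = "CATG") {
  stopifnot(min_len <= max_len, min_len >= 0L, nchar(anchor) >= 1L)
  .check_dna(sequence)
  if (nchar(sequence) < 2L * nchar(anchor)) return(character(0))
  hits <- gregexpr(anchor, sequence, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L || length(hits) < 2L) return(character(0))
  starts <- hits[-length(hits)] + nchar(anchor)
  ends <- hits[-1L] - 1L
  keep <- ends - starts + 1L >= min_len & ends - starts + 1L <= max_len
  if (!any(keep)) return(character(0))
  substring(sequence, starts[keep], ends[keep])
}

#' Split a ditag into its two constituent tags
#'
#' The first tag is the leading \code{tag_len} bases; the second tag is the
#' reverse complement of the trailing \code{tag_len} bases.  Ditags between
#' \code{tag_len} and \code{2 * tag_len} bases therefore yield two
#' overlapping tags; ditags shorter than \code{tag_len} are invalid.
#'
#' @param ditag a single ditag sequence.
#' @param tag_len tag length, default 10.
#' @return character vector of length 2: \code{c(first, second)}.
#' @examples
#' split_ditag("AAAAAAAAAATTTTTTTTTT")
#' @export
split_ditag <- function(ditag, tag_len = 10L) {
  .check_dna(ditag)
  n <- nchar(ditag)
  if (n < tag_len) {
    stop("ditag shorter than tag_len (", n, " < ", tag_len, ")",
         call. = FALSE)
  }
  c(substr(ditag, 1L, tag_len),
    revcomp(substr(ditag, n - tag_len + 1L, n)))
}

# vectorised splitter used by count_tags; short ditags return NA pairs
.split_ditags <- function(ditags, tag_len) {
  n <- nchar(ditags)
  ok <- n >= tag_len
  first <- ifelse(ok, substr(ditags, 1L, tag_len), NA_character_)
  second <- rep(NA_character_, length(ditags))
  if (any(ok)) {
    second[ok] <- revcomp(substr(ditags[ok], n[ok] - tag_len + 1L, n[ok]))
  }
  list(first = first, second = second, n_short = sum(!ok))
}

#' Construct a SAGE tag library
#'
#' @param counts named numeric vector of non-negative integer tag counts;
#'   names are fixed-length DNA tags without N.  Zero-count entries are
#'   dropped.
#' @param library_id library identifier.
#' @param tag_len expected tag length.
#' @param metadata free-form list (tissue site, pathology, ...).
#' @param stats optional list of processing totals (kept as an attribute in
#'   the JSON sidecar on write).
#' @return an object of class \code{tag_library} with elements
#'   \code{library_id}, \code{counts}, \code{total_tags}, \code{tag_len},
#'   \code{metadata}, \code{stats}.
#' @export
tag_library <- function(counts, library_id = "library", tag_len = 10L,
                        metadata = list(), stats = list()) {
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("counts must be named by tag", call. = FALSE)
    }
    counts <- counts[counts > 0]
  }
  if (length(counts)) {
    tags <- names(counts)
    if (any(nchar(tags) != tag_len)) {
      stop("all tags must have length ", tag_len, call. = FALSE)
    }
    if (any(grepl("N", tags, fixed = TRUE))) {
      stop("tags must not contain N", call. = FALSE)
    }
    if (any(counts != round(counts)) || any(counts < 1)) {
      stop("tag counts must be positive integers", call. = FALSE)
    }
    if (anyDuplicated(tags)) stop("duplicate tags in counts", call. = FALSE)
  }
  structure(list(library_id = library_id,
                 counts = counts,
                 total_tags = as.integer(sum(counts)),
                 tag_len = as.integer(tag_len),
                 metadata = metadata,
                 stats = stats),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat("SAGE tag library '", x$library_id, "': ", length(x$counts),
      " distinct tags, ", x$total_tags, " total tags (tag length ",
      x$tag_len, ")\n", sep = "")
  invisible(x)
}

#' Count tags from a set of ditags
#'
#' Optionally collapses exact duplicate ditags to a single occurrence first
#' (the classical PCR-duplicate control), then splits each ditag into its two
#' tags and tallies them.  Tags containing N and tags on the linker blacklist
#' are discarded; both are counted in the returned \code{stats}.
#'
#' @param ditags character vector of ditag sequences (e.g. from
#'   \code{\link{extract_ditags}}).
#' @param tag_len tag length, default 10.
#' @param dedupe collapse exact duplicate ditags before splitting
#'   (default TRUE).
#' @param linker_blacklist character vector of tag sequences to exclude.
#' @inheritParams tag_library
#' @return a \code{\link{tag_library}}; its \code{stats} element records
#'   \code{n_ditags_raw}, \code{n_ditags_used}, \code{n_short_rejected},
#'   \code{n_tags_with_N}, \code{n_blacklisted}.
#' @export
count_tags <- function(ditags, tag_len = 10L, dedupe = TRUE,
                       linker_blacklist = character(0),
                       library_id = "library", metadata = list()) {
  n_raw <- length(ditags)
  if (dedupe) ditags <- unique(ditags)
  n_used <- length(ditags)
  if (n_used == 0L) {
    return(tag_library(numeric(0), library_id = library_id,
                       tag_len = tag_len, metadata = metadata,
                       stats = list(n_ditags_raw = n_raw, n_ditags_used = 0L,
                                    n_short_rejected = 0L, n_tags_with_N = 0L,
                                    n_blacklisted = 0L)))
  }
  sp <- .split_ditags(ditags, tag_len)
  if (sp$n_short > 0L) {
    warning(sp$n_short, " ditag(s) shorter than tag_len rejected",
            call. = FALSE)
  }
  tags <- c(sp$first, sp$second)
  tags <- tags[!is.na(tags)]
  with_n <- grepl("N", tags, fixed = TRUE)
  if (any(with_n)) {
    warning(sum(with_n), " tag(s) containing N discarded", call. = FALSE)
  }
  tags <- tags[!with_n]
  blacklisted <- tags %in% linker_blacklist
  tags <- tags[!blacklisted]
  counts <- table(tags)
  tag_library(setNames(as.numeric(counts), names(counts)),
              library_id = library_id, tag_len = tag_len,
              metadata = metadata,
              stats = list(n_ditags_raw = n_raw,
                           n_ditags_used = n_used,
                           n_short_rejected = sp$n_short,
                           n_tags_with_N = sum(with_n),
                           n_blacklisted = sum(blacklisted)))
}

#' Construct a tag-to-gene map
#'
#' @param tags character vector of tags.
#' @param gene_ids character vector of gene identifiers, parallel to
#'   \code{tags}.  A tag appearing with more than one distinct gene is
#'   classified as ambiguous.
#' @return an object of class \code{tag_map} with elements \code{entries}
#'   (named character vector, unambiguous tag to gene), \code{ambiguous}
#'   (named list, tag to character vector of genes, in input order).
#' @export
tag_map <- function(tags, gene_ids) {
  stopifnot(length(tags) == length(gene_ids))
  if (any(!nzchar(gene_ids))) stop("gene_ids must be non-empty", call. = FALSE)
  uniq <- !duplicated(paste(tags, gene_ids, sep = "\r"))
  tags <- tags[uniq]; gene_ids <- gene_ids[uniq]
  by_tag <- split(gene_ids, factor(tags, levels = unique(tags)))
  n_genes <- lengths(by_tag)
  entries <- vapply(by_tag[n_genes == 1L], `[[`, character(1), 1L)
  structure(list(entries = entries, ambiguous = by_tag[n_genes > 1L]),
            class = "tag_map")
}

#' @export
print.tag_map <- function(x, ...) {
  cat("tag-to-gene map:", length(x$entries), "unambiguous tags,",
      length(x$ambiguous), "ambiguous tags\n")
  invisible(x)
}

#' Aggregate a tag library to per-gene counts
#'
#' Counts of tags mapping to the same gene are summed.  Tags absent from the
#' map contribute to the unmapped total; ambiguous tags are dropped by
#' default (preventing double counting) or assigned to the first gene listed
#' in the source table.
#'
#' @param lib a \code{\link{tag_library}}.
#' @param mapping a \code{\link{tag_map}}.
#' @param ambiguous_policy \code{"drop"} (default) or \code{"keep_first"}.
#' @return an object of class \code{gene_counts}: list with \code{counts}
#'   (named numeric per-gene vector), \code{unmapped_total},
#'   \code{ambiguous_total} (tags dropped under the \code{"drop"} policy),
#'   \code{total_input} (= \code{lib$total_tags}), \code{library_id}.
#'   Conservation: \code{sum(counts) + unmapped_total + ambiguous_total ==
#'   total_input}.
#' @export
aggregate_to_genes <- function(lib, mapping,
                               ambiguous_policy = c("drop", "keep_first")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  stopifnot(inherits(lib, "tag_library"), inherits(mapping, "tag_map"))
  tags <- names(lib$counts)
  cnt <- lib$counts
  gene <- unname(mapping$entries[tags])
  is_amb <- tags %in% names(mapping$ambiguous)
  ambiguous_total <- 0
  if (any(is_amb)) {
    if (ambiguous_policy == "keep_first") {
      gene[is_amb] <- vapply(mapping$ambiguous[tags[is_amb]], `[[`,
                             character(1), 1L)
    } else {
      ambiguous_total <- sum(cnt[is_amb])
      gene[is_amb] <- NA_character_
    }
  }
  unmapped_total <- sum(cnt[is.na(gene) & !is_amb])
  keep <- !is.na(gene)
  counts <- if (any(keep)) {
    rs <- rowsum(cnt[keep], group = gene[keep])
    setNames(as.numeric(rs), rownames(rs))
  } else numeric(0)
  structure(list(counts = counts,
                 unmapped_total = unname(unmapped_total),
                 ambiguous_total = unname(ambiguous_total),
                 ambiguous_policy = ambiguous_policy,
                 total_input = lib$total_tags,
                 library_id = lib$library_id),
            class = "gene_counts")
}

#' @export
print.gene_counts <- function(x, ...) {
  cat("gene counts for '", x$library_id, "': ", length(x$counts), " genes, ",
      sum(x$counts), " mapped tags (", x$unmapped_total, " unmapped, ",
      x$ambiguous_total, " ambiguous dropped)\n", sep = "")
  invisible(x)
}

# --- file interfaces ---------------------------------------------------------

#' Read concatemer reads from a FASTA file
#'
#' @param path FASTA file of concatemer reads.
#' @return named character vector of sequences (names = read ids).
#' @export
read_concatemer_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}

#' Extract and count tags from a FASTA file of concatemer reads
#'
#' Convenience wrapper: \code{\link{extract_ditags}} on every read followed
#' by \code{\link{count_tags}}.
#'
#' @inheritParams extract_ditags
#' @inheritParams count_tags
#' @param path FASTA file of concatemer reads.
#' @return a \code{\link{tag_library}}.
#' @export
count_tags_fasta <- function(path, tag_len = 10L, min_len = 20L,
                             max_len = 26L, anchor = "CATG", dedupe = TRUE,
                             linker_blacklist = character(0),
                             library_id = NULL, metadata = list()) {
  if (is.null(library_id)) {
    library_id <- tools::file_path_sans_ext(basename(path))
  }
  reads <- read_concatemer_fasta(path)
  ditags <- unlist(lapply(reads, extract_ditags, min_len = min_len,
                          max_len = max_len, anchor = anchor),
                   use.names = FALSE)
  count_tags(ditags, tag_len = tag_len, dedupe = dedupe,
             linker_blacklist = linker_blacklist, library_id = library_id,
             metadata = metadata)
}

#' Read a pre-counted tag table
#'
#' Expects a TSV with columns \code{tag} and \code{count} (header optional).
#'
#' @param path TSV file.
#' @param library_id library identifier; defaults to the file name.
#' @param tag_len expected tag length; inferred from the first tag if NULL.
#' @return a \code{\link{tag_library}}.
#' @export
read_tag_counts <- function(path, library_id = NULL, tag_len = NULL) {
  if (is.null(library_id)) {
    library_id <- tools::file_path_sans_ext(basename(path))
  }
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", col.names = c("tag", "count"))
  if (identical(tolower(df$tag[1L]), "tag")) df <- df[-1L, , drop = FALSE]
  df$count <- as.numeric(df$count)
  if (is.null(tag_len)) tag_len <- nchar(df$tag[1L])
  tag_library(setNames(df$count, df$tag), library_id = library_id,
              tag_len = tag_len)
}

#' Write a tag library to TSV (with JSON sidecar)
#'
#' Rows are sorted by descending count, ties broken by tag sequence.  A JSON
#' sidecar \code{<path>.json} records the totals and processing statistics.
#'
#' @param lib a \code{\link{tag_library}}.
#' @param path output TSV path.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_tag_counts <- function(lib, path, sidecar = TRUE) {
  stopifnot(inherits(lib, "tag_library"))
  ord <- order(-lib$counts, names(lib$counts))
  df <- data.frame(tag = names(lib$counts)[ord],
                   count = unname(lib$counts)[ord])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("tag", "count"))
  if (sidecar) {
    meta <- list(library_id = lib$library_id,
                 total_tags = lib$total_tags,
                 distinct_tags = length(lib$counts),
                 tag_len = lib$tag_len,
                 stats = lib$stats,
                 metadata = lib$metadata)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a tag-to-gene mapping table
#'
#' TSV with columns \code{tag} and \code{gene_id} (header optional); a tag
#' repeated with different genes becomes ambiguous.
#'
#' @param path TSV file.
#' @return a \code{\link{tag_map}}.
#' @export
read_tag_map <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character",
                   col.names = c("tag", "gene_id"))
  if (identical(tolower(df$tag[1L]), "tag")) df <- df[-1L, , drop = FALSE]
  tag_map(df$tag, df$gene_id)
}
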