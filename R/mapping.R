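# Tip associations and the reconciliation problem instance.

#' Parse a tip-association table
#'
#' Each line associates one gene (parasite) tip with one species (host) tip,
#' separated by a tab or a colon.  Lines starting with `#` and blank lines
#' are ignored.  The mapping must be total over the gene tips; many gene
#' tips may map to the same species tip.
#'
#' @param text the table as a single string (lines separated by `\n`) or a
#'   character vector of lines.
#' @param gene_tree,species_tree `rb_tree` objects.
#' @return a named character vector (gene tip label -> species tip label).
#' @export
parse_mapping <- function(text, gene_tree, species_tree) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- lapply(lines, function(ln) {
    p <- strsplit(ln, "\t|:")[[1]]
    p <- trimws(p[nzchar(trimws(p))])
    if (length(p) != 2) stop("malformed mapping line: '", ln, "'")
    p
  })
  g <- vapply(parts, `[`, character(1), 1)
  s <- vapply(parts, `[`, character(1), 2)
  gl <- gene_tree$labels[gene_tree$is_tip]
  sl <- species_tree$labels[species_tree$is_tip]
  probs <- character(0)
  dup <- unique(g[duplicated(g)])
  if (length(dup))
    probs <- c(probs, paste0("duplicate gene-leaf lines: ",
                             paste(dup, collapse = ", ")))
  unk_g <- setdiff(g, gl)
  if (length(unk_g))
    probs <- c(probs, paste0("unknown gene leaves: ",
                             paste(unk_g, collapse = ", ")))
  unk_s <- setdiff(s, sl)
  if (length(unk_s))
    probs <- c(probs, paste0("unknown species leaves: ",
                             paste(unk_s, collapse = ", ")))
  miss <- setdiff(gl, g)
  if (length(miss))
    probs <- c(probs, paste0("unmapped gene leaves: ",
                             paste(miss, collapse = ", ")))
  if (length(probs)) stop(paste(probs, collapse = "; "))
  stats::setNames(s, g)
}

#' Assemble a reconciliation problem instance
#'
#' Bundles the gene (parasite) tree, the species (host) tree and the tip
#' association into the instance object consumed by [pareto_reconcile()] and
#' the rest of the package.
#'
#' @param gene_tree,species_tree `rb_tree` objects (or Newick strings).
#' @param mapping a named character vector (gene tip -> species tip) or
#'   mapping text accepted by [parse_mapping()].
#' @return an object of class `recon_input`.
#' @examples
#' inp <- recon_input("(a,(b,c));", "((A,B),C);", c(a = "A", b = "B", c = "C"))
#' @export
recon_input <- function(gene_tree, species_tree, mapping) {
  if (is.character(gene_tree)) gene_tree <- parse_newick(gene_tree)
  if (is.character(species_tree)) species_tree <- parse_newick(species_tree)
  stopifnot(inherits(gene_tree, "rb_tree"), inherits(species_tree, "rb_tree"))
  if (is.character(mapping) && is.null(names(mapping)))
    mapping <- parse_mapping(mapping, gene_tree, species_tree)
  if (is.null(names(mapping))) stop("mapping must be named or parseable text")
  m <- parse_mapping(paste(names(mapping), unname(mapping), sep = "\t",
                           collapse = "\n"),
                     gene_tree, species_tree)
  # leaf map by node id: gene tip id -> species tip id
  leaf_map <- rep(NA_integer_, gene_tree$n_node)
  for (g in names(m))
    leaf_map[tip_id(gene_tree, g)] <- tip_id(species_tree, m[[g]])
  structure(list(gene = gene_tree, species = species_tree,
                 mapping = m, leaf_map = leaf_map),
            class = "recon_input")
}

#' @export
print.recon_input <- function(x, ...) {
  cat("DTL reconciliation instance\n")
  cat("  species (host) tree:   ", write_newick(x$species), "\n", sep = "")
  cat("  gene (parasite) tree:  ", write_newick(x$gene), "\n", sep = "")
  cat("  tip associations:      ", length(x$mapping), "\n", sep = "")
  invisible(x)
}

#' Read a reconciliation instance from files
#'
#' Either three files (host tree, parasite tree, mapping TSV) or a single
#' combined file with section headers `HOSTTREE`, `PARASITETREE`, `MAPPING`,
#' each on its own line followed by the section body.
#'
#' @param host,parasite,mapping paths to the host (species) Newick, parasite
#'   (gene) Newick, and tip-association table.
#' @param combined path to a combined file; overrides the other arguments.
#' @return a `recon_input`.
#' @export
read_recon_input <- function(host = NULL, parasite = NULL, mapping = NULL,
                             combined = NULL) {
  if (!is.null(combined)) {
    lines <- readLines(combined)
    tag <- toupper(trimws(lines))
    hdr <- which(tag %in% c("HOSTTREE", "PARASITETREE", "MAPPING"))
    if (length(hdr) != 3) stop("combined file needs HOSTTREE, PARASITETREE ",
                               "and MAPPING sections")
    bounds <- c(hdr, length(lines) + 1L)
    sec <- list()
    for (i in seq_along(hdr))
      sec[[tag[hdr[i]]]] <- lines[(hdr[i] + 1L):(bounds[i + 1L] - 1L)]
    host_txt <- paste(sec$HOSTTREE, collapse = "")
    para_txt <- paste(sec$PARASITETREE, collapse = "")
    map_txt <- paste(sec$MAPPING, collapse = "\n")
  } else {
    if (is.null(host) || is.null(parasite) || is.null(mapping))
      stop("need host, parasite and mapping files (or a combined file)")
    host_txt <- paste(readLines(host), collapse = "")
    para_txt <- paste(readLines(parasite), collapse = "")
    map_txt <- paste(readLines(mapping), collapse = "\n")
  }
  S <- parse_newick(host_txt)
  G <- parse_newick(para_txt)
  recon_input(G, S, parse_mapping(map_txt, G, S))
}
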