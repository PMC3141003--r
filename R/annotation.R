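## Probe annotation: origin of each spotted oligo (cnidarian host,
## zooxanthellar symbiont, or prokaryote), a functional role label and a
## small set of GO terms. The consensus gene-set selection and the tissue
## Venn both restrict to cnidarian-origin probes, so origin is the one
## column every downstream stage depends on.

# Fixed GO vocabulary the simulator samples from. Terms are the functional
# classes recurrent in host-symbiont expression studies (plastid-derived
# signal, calcium binding, vesicle traffic, ...); ids are real GO ids so
# annotation files look like Blast2GO output.
go_vocabulary <- function() {
  c("GO:0005509|calcium ion binding",
    "GO:0009536|plastid",
    "GO:0005829|cytosol",
    "GO:0016023|cytoplasmic membrane-bounded vesicle",
    "GO:0006351|transcription",
    "GO:0036211|protein modification process",
    "GO:0007155|cell adhesion",
    "GO:0006629|lipid metabolic process",
    "GO:0006810|transport",
    "GO:0006950|response to stress",
    "GO:0016192|vesicle-mediated transport",
    "GO:0004089|carbonate dehydratase activity",
    "GO:0016209|antioxidant activity",
    "GO:0005576|extracellular region",
    "GO:0005739|mitochondrion",
    "GO:0005764|lysosome",
    "GO:0008152|metabolic process",
    "GO:0006508|proteolysis",
    "GO:0005215|transporter activity",
    "GO:0016567|protein ubiquitination")
}

role_vocabulary <- function() {
  c("cell adhesion", "metabolism-FA", "metabolism", "pH homeostasis",
    "Ca2+ binding", "vesicle", "antioxidant", "Ubiquitin pathway",
    "ion transport", "receptor signaling", "RNA processing", "DNA damage",
    "detoxification", "solute transporter", "collagen processing",
    "unknown")
}

#' Generate a synthetic probe annotation table
#'
#' Builds a per-probe annotation with taxon origin drawn exactly in the
#' requested proportions, a functional role, and GO terms sampled
#' reproducibly from a fixed vocabulary. Origins follow the array's makeup:
#' host (cnidarian) probes plus symbiont (zooxanthella) and prokaryote
#' controls, which downstream consensus selection excludes.
#'
#' @param n_cnidarian,n_zoox,n_prok number of probes of each origin.
#' @param go_terms_per_gene GO terms drawn per probe (0 for none).
#' @param seed integer seed; identical seeds give identical tables.
#' @return A data.frame with columns `probe_id`, `origin`
#'   (`cnidarian`/`zooxanthella`/`prokaryote`), `name`, `role`, `go_terms`
#'   (semicolon-separated GO ids).
#' @examples
#' ann <- generate_annotation(100, 10, 5, go_terms_per_gene = 2, seed = 1)
#' table(ann$origin)
#' @export
generate_annotation <- function(n_cnidarian, n_zoox, n_prok,
                                go_terms_per_gene = 2, seed = 1) {
  check_counts(n_cnidarian = n_cnidarian, n_zoox = n_zoox, n_prok = n_prok,
               go_terms_per_gene = go_terms_per_gene)
  n <- n_cnidarian + n_zoox + n_prok
  if (n == 0L) {
    return(data.frame(probe_id = character(), origin = character(),
                      name = character(), role = character(),
                      go_terms = character(), stringsAsFactors = FALSE))
  }
  with_seed(sub_seed(seed, 11L), {
    origin <- sample(rep(c("cnidarian", "zooxanthella", "prokaryote"),
                         times = c(n_cnidarian, n_zoox, n_prok)))
    probe_id <- sprintf("AvCL%05d", seq_len(n))
    role <- sample(role_vocabulary(), n, replace = TRUE)
    vocab <- sub("\\|.*", "", go_vocabulary())
    go_terms <- if (go_terms_per_gene > 0) {
      k <- min(go_terms_per_gene, length(vocab))
      vapply(seq_len(n), function(i)
        paste(sample(vocab, k), collapse = ";"), character(1))
    } else rep("", n)
    data.frame(probe_id = probe_id, origin = origin,
               name = sprintf("gene_%05d", seq_len(n)), role = role,
               go_terms = go_terms, stringsAsFactors = FALSE)
  })
}

## Expand the semicolon-packed go_terms column to long (gene, term) form.
annotation_go_long <- function(annotation) {
  terms <- strsplit(annotation$go_terms, ";", fixed = TRUE)
  n <- lengths(terms)
  out <- data.frame(probe_id = rep(annotation$probe_id, n),
                    term = unlist(terms), stringsAsFactors = FALSE)
  out[nzchar(out$term), , drop = FALSE]
}
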