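# Fixture karyotypes mirroring the two reciprocal translocations under
# study (2/8 with novel breakpoint segments x/y and lost micro-segments
# b/e; 1/9 with duplicated segments h/k1/k3 and a heterozygous k2 loss).

karyotype28 <- function() {
    karyotypeModel(
        segments = data.frame(
            name   = c("a", "b", "c", "d", "e", "f", "x", "y"),
            length = c(5e4, 1200, 5e4, 5e4, 3000, 5e4, 600, 1200),
            origin = c("chr2", "chr2", "chr2", "chr8", "chr8", "chr8",
                       "novel", "novel")),
        structures = list(chr2 = c("a", "b", "c"),
                          chr8 = c("d", "e", "f"),
                          `2T8` = c("a", "x", "f"),
                          `8T2` = c("d", "y", "c")),
        groups = list(`2/8` = list(ref = c("chr2", "chr8"),
                                   alt = c("2T8", "8T2"),
                                   absent = c("b", "e"))))
}

karyotype19 <- function() {
    karyotypeModel(
        segments = data.frame(
            name   = c("g", "h", "i", "j", "k1", "k2", "k3", "l"),
            length = 5e4,
            origin = c("chr1", "chr1", "chr1",
                       "chr9", "chr9", "chr9", "chr9", "chr9")),
        structures = list(chr1 = c("g", "h", "i"),
                          chr9 = c("j", "k1", "k2", "k3", "l"),
                          `1T9` = c("g", "h", "k1", "k2", "k3", "l"),
                          `9T1` = c("j", "k1", "k3", "h", "i")),
        groups = list(`1/9` = list(ref = c("chr1", "chr9"),
                                   alt = c("1T9", "9T1"))))
}

# Constraint set for the 1/9 reconstruction: cluster-derived adjacencies
# (h-k1; the k2-deletion junction k1-k3; the cluster linking the k1-k3
# deletion fragment to h, i.e. the run k1-k3-h), retained reference
# adjacencies, chromosome-end anchors, and the heterozygous k2 loss.
constraints19 <- function(pairwiseOnly = FALSE) {
    req <- list(c("k3", "h"), c("h", "k1"), c("k1", "k3"),
                c("g", "h"), c("k1", "k2"), c("k2", "k3"),
                c("k3", "l"), c("h", "i"), c("j", "k1"))
    cons <- c(lapply(req, function(p)
                  adjacencyConstraint("required_adjacency", p)),
              list(adjacencyConstraint("anchor_start", "g"),
                   adjacencyConstraint("anchor_start", "j"),
                   adjacencyConstraint("anchor_end", "i"),
                   adjacencyConstraint("anchor_end", "l"),
                   adjacencyConstraint("heterozygous_deletion", "k2")))
    if (!pairwiseOnly)
        cons <- c(cons,
                  list(adjacencyConstraint("required_run",
                                           c("k1", "k3", "h"))))
    cons
}

constraints28 <- function() {
    list(adjacencyConstraint("required_adjacency", c("a", "f")),
         adjacencyConstraint("required_adjacency", c("d", "c")),
         adjacencyConstraint("anchor_start", "a"),
         adjacencyConstraint("anchor_start", "d"),
         adjacencyConstraint("anchor_end", "f"),
         adjacencyConstraint("anchor_end", "c"),
         adjacencyConstraint("absent_segment", "b"),
         adjacencyConstraint("absent_segment", "e"))
}

# Constraints implied by a set of true structures: all their adjacencies
# as required, their extremities as anchors.
constraintsFromStructures <- function(structures) {
    cons <- list()
    for (p in structures) {
        if (length(p) > 1L)
            for (i in seq_len(length(p) - 1L))
                cons <- c(cons, list(adjacencyConstraint(
                    "required_adjacency", c(p[i], p[i + 1L]))))
        cons <- c(cons, list(adjacencyConstraint("anchor_start", p[1L]),
                             adjacencyConstraint("anchor_end",
                                                 p[length(p)])))
    }
    cons
}
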