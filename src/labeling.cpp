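#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& parent, int i) {
    while (parent[i] != i) {
        parent[i] = parent[parent[i]];
        i = parent[i];
    }
    return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
    int ra = uf_find(parent, a), rb = uf_find(parent, b);
    if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

// Two-pass connected-component labeling of a logical matrix.
// connectivity is 4 or 8; labels are assigned in row-major scan order of
// each component's first pixel (origin top-left), starting at 1;
// background pixels get 0.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
    const int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    std::vector<int> parent;
    parent.reserve(1024);
    parent.push_back(0); // label 0 = background sentinel

    for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
            if (!mask(r, c)) continue;
            int best = 0;
            // previously scanned neighbours (row-major order)
            int up = (r > 0 && mask(r - 1, c)) ? lab(r - 1, c) : 0;
            int left = (c > 0 && mask(r, c - 1)) ? lab(r, c - 1) : 0;
            int ul = 0, ur = 0;
            if (connectivity == 8 && r > 0) {
                if (c > 0 && mask(r - 1, c - 1)) ul = lab(r - 1, c - 1);
                if (c + 1 < nc && mask(r - 1, c + 1)) ur = lab(r - 1, c + 1);
            }
            int neigh[4] = { up, left, ul, ur };
            for (int k = 0; k < 4; ++k)
                if (neigh[k] > 0 && (best == 0 || neigh[k] < best)) best = neigh[k];
            if (best == 0) {
                int lbl = (int) parent.size();
                parent.push_back(lbl);
                lab(r, c) = lbl;
            } else {
                lab(r, c) = best;
                for (int k = 0; k < 4; ++k)
                    if (neigh[k] > 0 && neigh[k] != best)
                        uf_union(parent, neigh[k], best);
            }
        }
    }

    // Resolve equivalences, then renumber by first appearance in scan order.
    std::vector<int> remap(parent.size(), 0);
    int next_id = 0;
    for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
            int l = lab(r, c);
            if (l == 0) continue;
            int root = uf_find(parent, l);
            if (remap[root] == 0) remap[root] = ++next_id;
            lab(r, c) = remap[root];
        }
    }
    return lab;
}
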