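#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// FP-growth frequent itemset miner over integer-coded transactions.
//
// Transactions are clusters of genomic bins; itemsets of size k are
// candidate k-way contacts and the support of an itemset is the number of
// clusters containing all of its bins.  The tree compresses shared prefixes
// of transactions (items ordered by decreasing global support, ties broken
// by ascending item id, for determinism) and frequent sets are grown
// bottom-up over conditional pattern bases, exploiting the Apriori
// anti-monotonicity of support.

namespace {

struct FPNode {
    int item;                 // item id (position in the global order)
    long long count;
    int parent;               // index into node pool, -1 for root
    std::unordered_map<int, int> children;
};

class FPTree {
public:
    std::vector<FPNode> nodes;
    // header[item] -> node indices holding that item
    std::unordered_map<int, std::vector<int> > header;

    FPTree() {
        FPNode root;
        root.item = -1;
        root.count = 0;
        root.parent = -1;
        nodes.push_back(root);
    }

    // tx must already be sorted in the global item order
    void insert(const std::vector<int>& tx, long long cnt) {
        int cur = 0;
        for (size_t t = 0; t < tx.size(); ++t) {
            int it = tx[t];
            std::unordered_map<int, int>::iterator f = nodes[cur].children.find(it);
            int nxt;
            if (f == nodes[cur].children.end()) {
                nxt = (int)nodes.size();
                FPNode nd;
                nd.item = it;
                nd.count = 0;
                nd.parent = cur;
                nodes.push_back(nd);
                nodes[cur].children[it] = nxt;
                header[it].push_back(nxt);
            } else {
                nxt = f->second;
            }
            nodes[nxt].count += cnt;
            cur = nxt;
        }
    }
};

struct MineOutput {
    std::vector< std::vector<int> > itemsets;  // original item labels
    std::vector<long long> supports;
};

// Recursively mine `tree`; `suffix` holds original item labels already fixed.
void mine(const FPTree& tree, std::vector<int>& suffix,
          long long minsup, int kmin, int kmax, MineOutput& out)
{
    // collect items present, with their conditional supports
    std::vector< std::pair<int, long long> > items;
    items.reserve(tree.header.size());
    for (std::unordered_map<int, std::vector<int> >::const_iterator it = tree.header.begin();
         it != tree.header.end(); ++it) {
        long long s = 0;
        for (size_t n = 0; n < it->second.size(); ++n)
            s += tree.nodes[it->second[n]].count;
        if (s >= minsup) items.push_back(std::make_pair(it->first, s));
    }
    // deterministic order: ascending item id
    std::sort(items.begin(), items.end());

    for (size_t idx = 0; idx < items.size(); ++idx) {
        int item = items[idx].first;
        long long sup = items[idx].second;
        suffix.push_back(item);
        int len = (int)suffix.size();
        if (len >= kmin && len <= kmax) {
            out.itemsets.push_back(suffix);
            out.supports.push_back(sup);
        }
        if (len < kmax) {
            // conditional pattern base for `item`
            FPTree cond;
            const std::vector<int>& occ = tree.header.find(item)->second;
            for (size_t n = 0; n < occ.size(); ++n) {
                long long cnt = tree.nodes[occ[n]].count;
                std::vector<int> path;
                int p = tree.nodes[occ[n]].parent;
                while (p > 0) {
                    path.push_back(tree.nodes[p].item);
                    p = tree.nodes[p].parent;
                }
                if (!path.empty()) {
                    std::reverse(path.begin(), path.end());
                    cond.insert(path, cnt);
                }
            }
            if (!cond.header.empty())
                mine(cond, suffix, minsup, kmin, kmax, out);
        }
        suffix.pop_back();
    }
}

}  // namespace

// [[Rcpp::export(name = ".fpgrowth_mine")]]
List fpgrowth_mine(List transactions, double minsup, int kmin, int kmax)
{
    long long ms = (long long)minsup;
    if (ms < 1) stop("minimum support must be >= 1");
    int ntx = transactions.size();

    // global item supports (count each item once per transaction; callers
    // guarantee deduplicated transactions)
    std::unordered_map<int, long long> gsup;
    std::vector< std::vector<int> > txs(ntx);
    for (int i = 0; i < ntx; ++i) {
        IntegerVector tv = transactions[i];
        std::vector<int>& tx = txs[i];
        tx.assign(tv.begin(), tv.end());
        for (size_t t = 0; t < tx.size(); ++t) gsup[tx[t]] += 1;
    }

    // global order: descending support, ties ascending item id
    std::vector< std::pair<int, long long> > freq;
    for (std::unordered_map<int, long long>::iterator it = gsup.begin(); it != gsup.end(); ++it)
        if (it->second >= ms) freq.push_back(std::make_pair(it->first, it->second));
    struct Cmp {
        bool operator()(const std::pair<int, long long>& a,
                        const std::pair<int, long long>& b) const {
            if (a.second != b.second) return a.second > b.second;
            return a.first < b.first;
        }
    };
    std::sort(freq.begin(), freq.end(), Cmp());
    std::unordered_map<int, int> rank;   // item -> position in order
    std::vector<int> label(freq.size()); // position -> item
    for (size_t i = 0; i < freq.size(); ++i) {
        rank[freq[i].first] = (int)i;
        label[i] = freq[i].first;
    }

    FPTree tree;
    std::vector<int> coded;
    for (int i = 0; i < ntx; ++i) {
        coded.clear();
        for (size_t t = 0; t < txs[i].size(); ++t) {
            std::unordered_map<int, int>::iterator f = rank.find(txs[i][t]);
            if (f != rank.end()) coded.push_back(f->second);
        }
        if (coded.empty()) continue;
        std::sort(coded.begin(), coded.end());
        tree.insert(coded, 1);
    }

    MineOutput out;
    std::vector<int> suffix;
    mine(tree, suffix, ms, kmin, kmax, out);

    // translate coded items back to labels and sort bins within itemsets
    List sets(out.itemsets.size());
    NumericVector sups(out.itemsets.size());
    for (size_t i = 0; i < out.itemsets.size(); ++i) {
        std::vector<int> s(out.itemsets[i].size());
        for (size_t t = 0; t < s.size(); ++t) s[t] = label[out.itemsets[i][t]];
        std::sort(s.begin(), s.end());
        sets[i] = IntegerVector(s.begin(), s.end());
        sups[i] = (double)out.supports[i];
    }
    return List::create(_["itemsets"] = sets, _["support"] = sups);
}
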