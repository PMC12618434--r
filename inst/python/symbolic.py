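"""Computer-algebra helper: exact polynomial operations over the rationals.

Reads a JSON list of requests on stdin, writes a JSON list of responses on
stdout. Each request is {"op": ..., ...}; each response either carries the
op's payload or {"error": message}. Expressions travel as strings in the
package's model-file grammar (integers, p/q rationals, + - * / ** ^).
"""

import json
import sys

import sympy as sp
from sympy.parsing.sympy_parser import parse_expr, standard_transformations, convert_xor

TRANSFORMS = standard_transformations + (convert_xor,)


def parse(expr, symbols):
    local = {s: sp.Symbol(s) for s in symbols}
    e = parse_expr(expr, local_dict=local, transformations=TRANSFORMS, evaluate=True)
    bad = e.free_symbols - set(local.values())
    if bad:
        raise ValueError("undeclared symbols: %s" % sorted(map(str, bad)))
    return sp.expand(sp.together(e))


def poly_str(e):
    return str(sp.expand(e))


def irreducible_factors(expr, syms):
    """Distinct nonconstant irreducible factors over Q (squarefree, primitive)."""
    out = []
    if expr == 0:
        return out
    for fac, _mult in sp.factor_list(expr, *syms)[1]:
        fac = sp.expand(fac)
        if fac.is_number:
            continue
        p = sp.Poly(fac, *syms, domain="QQ")
        _, prim = p.clear_denoms()
        prim = prim.primitive()[1]
        if prim.LC() < 0:
            prim = -prim
        out.append(poly_str(prim.as_expr()))
    seen, uniq = set(), []
    for f in out:
        if f not in seen:
            seen.add(f)
            uniq.append(f)
    return uniq


def op_factor(req):
    syms = [sp.Symbol(s) for s in req["syms"]]
    e = parse(req["expr"], req["syms"])
    facs = irreducible_factors(e, syms)
    degs = [sp.Poly(parse(f, req["syms"]), *syms).total_degree() for f in facs]
    return {"factors": facs, "degrees": degs}


def groebner_basis(gens, syms):
    return sp.groebner([g for g in gens if g != 0], *syms, order="lex", domain="QQ")


def op_groebner(req):
    syms = [sp.Symbol(s) for s in req["syms"]]
    gens = [parse(g, req["syms"]) for g in req["gens"]]
    G = groebner_basis(gens, syms)
    return {"basis": [poly_str(b) for b in G.exprs]}


def op_decompose(req):
    """Decompose <polys> into components by fixed-point factor splitting."""
    names = req["vars"] + req["pars"]
    syms = [sp.Symbol(s) for s in names]
    polys = [parse(p, names) for p in req["polys"]]

    def reduce_mod(p, gens):
        gens = [g for g in gens if g != 0]
        if not gens:
            return sp.expand(p)
        G = groebner_basis(gens, syms)
        return sp.expand(G.reduce(p)[1])

    branches = [[list(), [sp.expand(p) for p in polys]]]  # [chosen gens, pending]
    done = []
    guard = 0
    while branches:
        guard += 1
        if guard > 10000:
            raise RuntimeError("factor splitting did not terminate")
        gens, pending = branches.pop()
        if not pending:
            # fixed point: re-factor each gen modulo the others until stable
            changed = False
            for i, g in enumerate(gens):
                rest = gens[:i] + gens[i + 1:]
                r = reduce_mod(g, rest)
                if r == 0:
                    nb = rest
                    if nb:
                        branches.append([list(nb), []])
                        changed = True
                    break
                if r.is_number:
                    changed = True  # inconsistent branch: drop
                    break
                facs = [f for f, _ in sp.factor_list(r, *syms)[1] if not f.is_number]
                if len(facs) > 1:
                    for f in facs:
                        branches.append([rest + [sp.expand(f)], []])
                    changed = True
                    break
                newg = sp.expand(facs[0])
                if newg != sp.expand(g) and str(newg) != str(sp.expand(g)):
                    gens = rest + [newg]
                    branches.append([gens, []])
                    changed = True
                    break
            if not changed:
                done.append(gens)
            continue
        p, rest = pending[0], pending[1:]
        r = reduce_mod(p, gens)
        if r == 0:
            branches.append([gens, rest])
            continue
        if r.is_number:
            continue  # inconsistent
        for fac, _ in sp.factor_list(r, *syms)[1]:
            if fac.is_number:
                continue
            branches.append([gens + [sp.expand(fac)], rest])

    # dedupe by reduced Groebner basis, then drop redundant branches whose
    # variety is contained in another component's variety
    comps = {}
    for gens in done:
        G = groebner_basis(gens, syms)
        key = tuple(sorted(str(e) for e in G.exprs))
        if key not in comps and sp.Integer(1) not in G.exprs:
            comps[key] = (gens, G)
    keys = list(comps)
    keep = []
    for i, ki in enumerate(keys):
        gi, Gi = comps[ki]
        redundant = False
        for j, kj in enumerate(keys):
            if i == j:
                continue
            gj, Gj = comps[kj]
            # V(i) subset of V(j) iff every generator of j reduces to 0 mod i
            if all(Gi.reduce(g)[1] == 0 for g in Gj.exprs) and ki != kj:
                # proper containment: some generator of i not in j
                if not all(Gj.reduce(g)[1] == 0 for g in Gi.exprs):
                    redundant = True
                    break
        if not redundant:
            keep.append(ki)
    return {"components": [{"gens": [poly_str(g) for g in comps[k][1].exprs]}
                           for k in keep]}


def triangular_eliminate(gens, target, vsy, psy):
    """Eliminate variables by back-substituting generators that are linear in
    some variable with a coefficient free of the remaining variables, then a
    final univariate resultant. Returns the eliminated polynomial in the
    parameters, or None when the structure does not triangularize."""
    gens = [sp.expand(g) for g in gens if g != 0]
    target = sp.expand(target)
    rem = list(vsy)
    while True:
        hit = None
        for g in gens:
            for v in rem:
                try:
                    p = sp.Poly(g, v)
                except sp.PolynomialError:
                    continue
                if p.degree() != 1:
                    continue
                a = p.coeff_monomial(v)
                if any(a.has(w) for w in rem if w != v):
                    continue
                hit = (g, v, sp.cancel(-sp.expand(g - a * v) / a))
                break
            if hit:
                break
        if hit is None:
            break
        g, v, sol = hit
        gens = [sp.numer(sp.cancel(h.subs(v, sol))) for h in gens if h is not g]
        gens = [sp.expand(h) for h in gens if h != 0]
        target = sp.numer(sp.cancel(target.subs(v, sol)))
        rem.remove(v)
    if not rem:
        return sp.expand(target)
    if len(rem) == 1 and len(gens) == 1:
        x = rem[0]
        P = sp.Poly(gens[0], x)
        T = sp.Poly(target, x)
        if T.degree() == 0:
            return sp.expand(target)
        return sp.expand(sp.resultant(P, T))
    return None


def op_eliminate(req):
    """Parameter-only consequences of <gens (+ extra)>: eliminate the state
    variables by a block (lex) order and return the irreducible factors of the
    hypersurface part of the elimination ideal."""
    names = req["vars"] + req["pars"]
    vsy = [sp.Symbol(s) for s in req["vars"]]
    psy = [sp.Symbol(s) for s in req["pars"]]
    gens = [parse(g, names) for g in req["gens"]]
    extra = req.get("extra")
    if extra:
        gens = gens + [parse(extra, names)]
    if req.get("strategy") == "triangular":
        tgt = gens[-1] if extra else sp.Integer(0)
        base = gens[:-1] if extra else gens
        elim = triangular_eliminate(base, tgt, vsy, psy)
        if elim is not None:
            if elim == 0:
                return {"factors": [], "zero_ideal": True, "codim_ge_2": False,
                        "inconsistent": False}
            if elim.is_number:
                return {"factors": [], "zero_ideal": False, "codim_ge_2": False,
                        "inconsistent": True}
            return {"factors": irreducible_factors(elim, psy),
                    "zero_ideal": False, "codim_ge_2": False,
                    "inconsistent": False}
        # fall through to Groebner when not triangularizable
    G = groebner_basis(gens, vsy + psy)
    if sp.Integer(1) in G.exprs:
        return {"factors": [], "zero_ideal": False, "codim_ge_2": False,
                "inconsistent": True}
    par_elems = [g for g in G.exprs if not any(g.has(v) for v in vsy)]
    if not par_elems:
        return {"factors": [], "zero_ideal": True, "codim_ge_2": False,
                "inconsistent": False}
    g = sp.Integer(0)
    for p in par_elems:
        g = sp.gcd(g, p)
    if g.is_number:
        return {"factors": [], "zero_ideal": False, "codim_ge_2": True,
                "inconsistent": False}
    return {"factors": irreducible_factors(g, psy), "zero_ideal": False,
            "codim_ge_2": False, "inconsistent": False}


def squarefree_real_roots(P, digits=30):
    P = sp.Poly(P.as_expr(), P.gens[0], domain="QQ")
    g = sp.gcd(P, P.diff(P.gens[0]))
    sf = P.quo(g) if g.total_degree() > 0 else P
    return [str(sp.N(r, digits)) for r in sf.real_roots()]


def op_real_roots_biv(req):
    """Real-root candidates of a bivariate square system via resultants."""
    u, v = [sp.Symbol(s) for s in req["vars"]]
    p1 = parse(req["p1"], req["vars"])
    p2 = parse(req["p2"], req["vars"])
    R1 = sp.Poly(sp.resultant(sp.Poly(p1, v), sp.Poly(p2, v)), u)
    R2 = sp.Poly(sp.resultant(sp.Poly(p1, u), sp.Poly(p2, u)), v)
    if R1.is_zero or R2.is_zero:
        return {"common_factor": True, "roots1": [], "roots2": []}
    return {"common_factor": False,
            "roots1": squarefree_real_roots(R1),
            "roots2": squarefree_real_roots(R2)}


def op_real_roots_uni(req):
    x = sp.Symbol(req["var"])
    p = parse(req["p"], [req["var"]])
    return {"roots": squarefree_real_roots(sp.Poly(p, x))}


def op_solve_system(req):
    """All complex solutions of a zero-dimensional square polynomial system
    (independent cross-check oracle for the package's own solver)."""
    names = req["vars"] + req.get("pars", [])
    syms = [sp.Symbol(s) for s in req["vars"]]
    polys = [parse(p, names) for p in req["polys"]]
    try:
        sols = sp.solve_poly_system(polys, *syms)
    except Exception as exc:  # positive-dimensional or unsupported
        return {"error": "solve failed: %s" % exc}
    out = []
    for s in sols:
        pt = []
        for comp in s:
            c = complex(sp.N(comp, 25))
            pt.extend([c.real, c.imag])
        out.append(pt)
    return {"solutions": out}


def op_resultant(req):
    names = req["syms"]
    syms = {s: sp.Symbol(s) for s in names}
    p = parse(req["p"], names)
    q = parse(req["q"], names)
    r = sp.resultant(sp.Poly(p, syms[req["var"]]), sp.Poly(q, syms[req["var"]]))
    return {"resultant": poly_str(r)}


OPS = {
    "factor": op_factor,
    "groebner": op_groebner,
    "decompose": op_decompose,
    "eliminate": op_eliminate,
    "real_roots_biv": op_real_roots_biv,
    "real_roots_uni": op_real_roots_uni,
    "solve_system": op_solve_system,
    "resultant": op_resultant,
}


def main():
    reqs = json.load(sys.stdin)
    out = []
    for req in reqs:
        try:
            out.append(OPS[req["op"]](req))
        except Exception as exc:
            out.append({"error": "%s: %s" % (type(exc).__name__, exc)})
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
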