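"""Exact polygon-clipping oracle for height-ranked visible crown cover.

Reads {"side": s, "maps": [[{"x","y","r","h"}, ...], ...]} on stdin and
prints, per map, the visible (unoccluded, plot-clipped) area of every tree
in record order. Taller crowns occlude shorter ones; height ties are won by
the earlier record, matching the rasterizer's tie rule.
"""
import sys, json
from shapely.geometry import Point, box
from shapely.ops import unary_union

data = json.load(sys.stdin)
side = data["side"]
plot = box(0.0, 0.0, side, side)
result = []
for trees in data["maps"]:
    order = sorted(range(len(trees)), key=lambda i: (-trees[i]["h"], i))
    taken = None
    vis = [0.0] * len(trees)
    for i in order:
        t = trees[i]
        disc = Point(t["x"], t["y"]).buffer(t["r"], quad_segs=256)
        visible = disc.intersection(plot)
        if taken is not None:
            visible = visible.difference(taken)
        vis[i] = visible.area
        taken = disc if taken is None else unary_union([taken, disc])
    result.append(vis)
print(json.dumps(result))
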