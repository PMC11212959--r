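# Toy probabilistic grammar over the toy lexicon. Non-recursive, so the
# language is finite; sentence lengths range from 4 to 15 words and
# 12-word sentences are reachable through many derivations.
S -> NP VP : 1.0
NP -> Det N : 0.5
NP -> Det AdjP N : 0.5
AdjP -> Adj : 0.7
AdjP -> Adj Adj : 0.3
VP -> Vt NP : 0.25
VP -> Vt NP PP : 0.3
VP -> Vi PP : 0.2
VP -> Vt NP PP Adv : 0.15
VP -> Vi Adv : 0.1
PP -> P NP : 1.0
Det -> the : 0.6
Det -> a : 0.4
Adj -> big : 0.2
Adj -> small : 0.2
Adj -> red : 0.15
Adj -> old : 0.15
Adj -> green : 0.15
Adj -> happy : 0.15
N -> cat : 0.1
N -> dog : 0.1
N -> bird : 0.08
N -> horse : 0.08
N -> teacher : 0.09
N -> student : 0.09
N -> river : 0.08
N -> garden : 0.08
N -> house : 0.08
N -> apple : 0.08
N -> engine : 0.07
N -> island : 0.07
Vt -> saw : 0.25
Vt -> liked : 0.2
Vt -> chased : 0.2
Vt -> found : 0.2
Vt -> admired : 0.15
Vi -> slept : 0.3
Vi -> smiled : 0.25
Vi -> vanished : 0.25
Vi -> waited : 0.2
P -> in : 0.3
P -> near : 0.25
P -> behind : 0.25
P -> above : 0.2
Adv -> quietly : 0.4
Adv -> quickly : 0.35
Adv -> slowly : 0.25
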