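# In-scanner stimulus list: 20 familiar words and 10 pronounceable
# pseudowords with ARPAbet-style phoneme transcriptions. origin = "attested"
# marks items named in the source literature; origin = "synthetic" marks
# generated padding items added to reach the design counts.
stimulus_id,condition,phonemes,origin
DOUGH,word,d oh,attested
TOUGH,word,t ah f,attested
SEW,word,s oh,attested
BREAD,word,b r eh d,attested
YACHT,word,y aa t,attested
EYE,word,ay,attested
YARN,word,y aa r n,attested
CLAM,word,k l ae m,attested
MINT,word,m ih n t,synthetic
FOLD,word,f oh l d,synthetic
SHADE,word,sh ey d,synthetic
PEARL,word,p er l,synthetic
GRAPE,word,g r ey p,synthetic
STONE,word,s t oh n,synthetic
WOOL,word,w uh l,synthetic
CHALK,word,ch ao k,synthetic
THUMB,word,th ah m,synthetic
VINE,word,v ay n,synthetic
SOAP,word,s oh p,synthetic
DRUM,word,d r ah m,synthetic
PENK,pseudoword,p eh ng k,attested
BRANE,pseudoword,b r ey n,attested
BRAME,pseudoword,b r ey m,attested
SNAB,pseudoword,s n ae b,synthetic
TROG,pseudoword,t r aa g,synthetic
PLIM,pseudoword,p l ih m,synthetic
DENK,pseudoword,d eh ng k,synthetic
FRAPE,pseudoword,f r ey p,synthetic
GOBE,pseudoword,g oh b,synthetic
SHULE,pseudoword,sh uw l,synthetic
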