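category	direction	pattern
negation	forward	no
negation	forward	without
negation	forward	no evidence of
negation	forward	no definite
negation	forward	absence of
negation	forward	free of
negation	forward	negative for
negation	backward	(?:is|are) not (?:seen|identified|present)
negation	backward	not (?:seen|identified|present|visualized)
negation	backward	(?:is|are) absent
uncertainty	forward	possible|possibly
uncertainty	forward	probable|probably
uncertainty	forward	suspicious for
uncertainty	forward	suspected|suspect
uncertainty	forward	may (?:represent|reflect|indicate)
uncertainty	forward	cannot (?:exclude|be excluded|rule out)
uncertainty	forward	questionable|question of
uncertainty	forward	concerning for|worrisome for
uncertainty	bidirectional	abut(?:s|ting)?
uncertainty	bidirectional	extend(?:s|ing)? towards?
uncertainty	bidirectional	in close (?:relation|proximity|contact) (?:to|with)
uncertainty	bidirectional	approach(?:es|ing)
uncertainty	bidirectional	border(?:s|ing)
historical	forward	prior
historical	forward	previous(?:ly)?
historical	forward	history of
historical	forward	status post
termination	bidirectional	but
termination	bidirectional	however
termination	bidirectional	although|though
termination	bidirectional	whereas
termination	bidirectional	aside from
termination	bidirectional	;
pseudo	forward	no (?:significant |interval |appreciable )?change
pseudo	forward	no longer
pseudo	forward	not excluded by prior
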