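THERAPIST: Last time we talked about your need for approval. Have
you noticed it this week?
CLIENT: I did. When my sister went to visit, I was so nervous
about what she would think of the apartment.
THERAPIST: And what did you tell yourself about it?
CLIENT: That it was ugly and that I am a mess. But maybe that is
not really true.
THERAPIST: That is very good. You are disputing it yourself now.
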