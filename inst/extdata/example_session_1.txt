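THERAPIST: So tell me about your week. Maybe we can start with
what happened with your mother.
CLIENT: It was really hard. I was so afraid to go and see her,
and I just never know what to say. [sighs]
THERAPIST: You were afraid. Perhaps we can stay with that feeling
for a moment.
CLIENT: Yeah. I guess it hurt, but I love her and I want things
to be good with us.
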